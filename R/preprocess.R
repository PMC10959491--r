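#' Air temperature at an arbitrary time, from hourly records
#'
#' Fits a natural cubic interpolating spline through the hourly readings of
#' each day and evaluates it at the requested timestamps. The spline passes
#' through every hourly knot exactly; no extrapolation outside a day's
#' covered hour range is permitted.
#'
#' @param weather data.frame with columns `date` (ISO-8601 `Date` or
#'   character), `hour` (0-23) and `air_t` (degrees C).
#' @param timestamps `POSIXct` vector (or ISO-8601 character) of query times.
#' @return Numeric vector of interpolated air temperatures (degrees C).
#' @examples
#' w <- data.frame(date = "2014-11-02", hour = 5:18,
#'                 air_t = seq(10, 36, length.out = 14))
#' interpolate_air_temperature(w, as.POSIXct("2014-11-02 09:30:00", tz = "UTC"))
#' @export
interpolate_air_temperature <- function(weather, timestamps) {
  weather <- validate_weather(weather)
  ts <- parse_timestamp(timestamps)
  qdate <- format(ts, "%Y-%m-%d", tz = "UTC")
  qhour <- as.numeric(format(ts, "%H", tz = "UTC")) +
    as.numeric(format(ts, "%M", tz = "UTC")) / 60 +
    as.numeric(format(ts, "%S", tz = "UTC")) / 3600
  out <- numeric(length(ts))
  for (d in unique(qdate)) {
    rows <- weather$date == d
    if (!any(rows)) stop("no weather records for date ", d)
    w <- weather[rows, ]
    if (nrow(w) < 4L) stop("fewer than 4 hourly readings on ", d)
    sel <- qdate == d
    h <- qhour[sel]
    if (any(h < min(w$hour) - 1e-9) || any(h > max(w$hour) + 1e-9)) {
      stop("timestamp outside covered hour range [", min(w$hour), ", ",
           max(w$hour), "] on ", d, " (no extrapolation)")
    }
    f <- stats::splinefun(w$hour, w$air_t, method = "natural")
    out[sel] <- f(h)
  }
  out
}

#' Head-neck surface-temperature deviation
#'
#' The study's measure of head thermoregulatory capacity for a given thermal
#' load: head surface temperature minus neck surface temperature from the
#' same image. Lower values under heat indicate stronger head cooling.
#'
#' @param head_t,neck_t surface temperatures (degrees C).
#' @return `head_t - neck_t` (degrees C).
#' @export
head_neck_deviation <- function(head_t, neck_t) {
  head_t - neck_t
}

#' Standardized temperature change away from the thermal optimum
#'
#' Air temperature is re-expressed as an absolute deviation from the optimum
#' (20 degrees C, where reproductive performance peaks), divided by the
#' maximum absolute deviation in the dataset so that 1 is the maximum
#' temperature change; a direction factor records whether the deviation is a
#' decrease or an increase. At exactly the optimum the change is 0 and the
#' direction is labelled `"decrease"` by convention (the zero change makes
#' the label inert).
#'
#' @param air_t air temperature (degrees C).
#' @param optimum thermal optimum (degrees C), default 20.
#' @param max_abs_dev normalizer: maximum `|air_t - optimum|` over the
#'   dataset the transform belongs to (degrees C, > 0).
#' @return List with `temp_change` (in `[0, 1]`) and `direction` (factor
#'   `decrease`/`increase`).
#' @export
temperature_change_transform <- function(air_t, optimum = 20, max_abs_dev) {
  stopifnot(max_abs_dev > 0)
  dev <- air_t - optimum
  if (any(abs(dev) > max_abs_dev + 1e-9)) {
    stop("|air_t - optimum| exceeds max_abs_dev: stale normalizer")
  }
  list(temp_change = pmin(abs(dev) / max_abs_dev, 1),
       direction = factor(ifelse(dev > 0, "increase", "decrease"),
                          levels = c("decrease", "increase")))
}

#' Air-temperature category
#'
#' Cold (air temperature at or below 20 degrees C), benign (between 20 and
#' 30), hot (30 or above).
#'
#' @param air_t air temperature (degrees C).
#' @return Factor with levels `cold`, `benign`, `hot`.
#' @export
assign_temperature_category <- function(air_t) {
  factor(ifelse(air_t <= 20, "cold", ifelse(air_t < 30, "benign", "hot")),
         levels = c("cold", "benign", "hot"))
}

#' Center and scale a covariate, optionally within groups
#'
#' Maps each group (or the whole series) to mean zero and unit sample
#' standard deviation. A constant series is an error.
#'
#' @param values numeric vector.
#' @param grouping optional factor of the same length.
#' @return Standardized numeric vector.
#' @export
standardize_covariate <- function(values, grouping = NULL) {
  scale1 <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("cannot standardize a constant series")
    (x - mean(x)) / s
  }
  if (is.null(grouping)) return(scale1(values))
  stopifnot(length(grouping) == length(values))
  out <- numeric(length(values))
  for (g in unique(grouping)) {
    sel <- grouping == g
    out[sel] <- scale1(values[sel])
  }
  out
}

#' Assemble model-ready thermal observations
#'
#' Converts raw image records plus hourly weather into one observation per
#' retained image: spline-interpolated air temperature at image time,
#' head-neck deviation, standardized temperature change and direction,
#' air-temperature category, within-category air-temperature deviation and
#' standardized time-of-day terms. Records violating range invariants
#' (surface temperatures outside \[-10, 60\] degrees C, time of day outside
#' the 05:00-18:00 imaging window, non-positive pixel counts) are dropped
#' and logged with reasons in the `"drops"` attribute. The temperature-change
#' normalizer is computed over the retained records and stored in the
#' `"max_abs_dev"` attribute.
#'
#' @param images data.frame with columns `image_id`, `individual_id`,
#'   `datetime` (ISO-8601), `head_t`, `neck_t`, optional `head_pixels`,
#'   `neck_pixels`, `enclosure`, `year`, optional `subspecies_class`.
#' @param weather hourly weather data.frame (`date`, `hour`, `air_t`).
#' @param optimum thermal optimum (degrees C).
#' @return data.frame of observations with attributes `drops` and
#'   `max_abs_dev`.
#' @export
build_observations <- function(images, weather, optimum = 20) {
  need <- c("image_id", "individual_id", "datetime", "head_t", "neck_t",
            "enclosure", "year")
  missing_cols <- setdiff(need, names(images))
  if (length(missing_cols)) {
    stop("images table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ts <- parse_timestamp(images$datetime)
  hour <- as.numeric(format(ts, "%H", tz = "UTC")) +
    as.numeric(format(ts, "%M", tz = "UTC")) / 60 +
    as.numeric(format(ts, "%S", tz = "UTC")) / 3600

  reason <- rep(NA_character_, nrow(images))
  flag <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }
  flag(is.na(images$individual_id) | !nzchar(as.character(images$individual_id)),
       "missing individual_id")
  flag(!is.finite(images$head_t) | images$head_t < -10 | images$head_t > 60,
       "head_t outside [-10, 60] C")
  flag(!is.finite(images$neck_t) | images$neck_t < -10 | images$neck_t > 60,
       "neck_t outside [-10, 60] C")
  flag(hour < 5 | hour > 18, "time of day outside 05:00-18:00 window")
  for (pc in c("head_pixels", "neck_pixels")) {
    if (pc %in% names(images)) {
      flag(!is.na(images[[pc]]) & images[[pc]] <= 0,
           paste(pc, "not positive"))
    }
  }
  keep <- is.na(reason)
  drops <- data.frame(image_id = images$image_id[!keep],
                      reason = reason[!keep], stringsAsFactors = FALSE)
  if (!any(keep)) stop("no valid images remain after validation")
  img <- images[keep, , drop = FALSE]
  ts <- ts[keep]

  air_t <- interpolate_air_temperature(weather, ts)
  max_abs_dev <- max(abs(air_t - optimum))
  if (max_abs_dev == 0) max_abs_dev <- 1  # all images exactly at the optimum
  tc <- temperature_change_transform(air_t, optimum, max_abs_dev)
  category <- assign_temperature_category(air_t)

  obs <- data.frame(
    image_id = as.character(img$image_id),
    individual_id = as.character(img$individual_id),
    date = format(ts, "%Y-%m-%d", tz = "UTC"),
    year = as.integer(img$year),
    enclosure_id = as.character(img$enclosure),
    air_t = air_t,
    head_t = img$head_t,
    neck_t = img$neck_t,
    head_neck_dev = head_neck_deviation(img$head_t, img$neck_t),
    temp_change = tc$temp_change,
    direction = tc$direction,
    tc_dec = tc$temp_change * (tc$direction == "decrease"),
    tc_inc = tc$temp_change * (tc$direction == "increase"),
    category = category,
    stringsAsFactors = FALSE
  )
  obs$subspecies_class <- if ("subspecies_class" %in% names(img)) {
    as.character(img$subspecies_class)
  } else "unknown"
  obs$within_category_dev <- standardize_safe(air_t, category)
  hrs <- as.numeric(format(ts, "%H", tz = "UTC")) +
    as.numeric(format(ts, "%M", tz = "UTC")) / 60 +
    as.numeric(format(ts, "%S", tz = "UTC")) / 3600
  obs$time_scaled <- standardize_safe(hrs)
  obs$time_scaled_sq <- obs$time_scaled^2
  attr(obs, "drops") <- drops
  attr(obs, "max_abs_dev") <- max_abs_dev
  attr(obs, "optimum") <- optimum
  obs
}

# --- internal helpers -------------------------------------------------------

# like standardize_covariate but degenerate groups (single observation or
# constant values) map to centered zeros instead of erroring
standardize_safe <- function(values, grouping = NULL) {
  if (is.null(grouping)) grouping <- rep(1L, length(values))
  out <- numeric(length(values))
  for (g in unique(grouping)) {
    sel <- grouping == g
    s <- stats::sd(values[sel])
    out[sel] <- if (!is.finite(s) || s == 0) 0 else
      (values[sel] - mean(values[sel])) / s
  }
  out
}

parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- sub("T", " ", as.character(x))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  if (anyNA(out)) stop("unparseable timestamp(s): ",
                       paste(utils::head(x[is.na(out)], 3L), collapse = ", "))
  out
}

validate_weather <- function(weather) {
  need <- c("date", "hour", "air_t")
  missing_cols <- setdiff(need, names(weather))
  if (length(missing_cols)) {
    stop("weather table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(weather$air_t) | weather$air_t < -20 | weather$air_t > 55)) {
    stop("weather air_t outside [-20, 55] C")
  }
  weather$date <- as.character(weather$date)
  weather[order(weather$date, weather$hour), ]
}
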