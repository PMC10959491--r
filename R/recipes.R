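# Declarative constructors for the package's analyses. Each recipe returns a
# `qg_recipe`: the model specification plus the prepared data frame (and
# pedigree where used), ready for qgfit().

new_recipe <- function(model, data, pedigree = NULL) {
  structure(list(model = model, data = data, pedigree = pedigree),
            class = "qg_recipe")
}

#' @export
#' @method print qg_recipe
print.qg_recipe <- function(x, ...) {
  cat("qg_recipe with", nrow(x$data), "rows\n")
  print(x$model)
  invisible(x)
}

subspecies_factor <- function(x) {
  pref <- c("SAB", "ZB", "KR", "hybrid", "unknown")
  levs <- c(intersect(pref, unique(x)), setdiff(sort(unique(x)), pref))
  factor(x, levels = levs)
}

category_factor <- function(x) factor(x, levels = c("cold", "benign", "hot"))

common_random <- function() {
  list(year = list(group = "year", design = "1"),
       enclosure = list(group = "enclosure_id", design = "1"),
       date = list(group = "date", design = "1"))
}

#' Binary egg-laying response lagged 2-4 days after imaging
#'
#' For each image event the response is 1 if at least one egg was laid on
#' any of days +2, +3 or +4 relative to the image date (the time an egg
#' takes to travel down the oviduct). Events whose window is not fully
#' covered by the laying records are dropped and logged in the `"drops"`
#' attribute.
#'
#' @param laying data.frame `female_id, date, egg_laid` (one row per
#'   female-day, `egg_laid` 0/1).
#' @param events data.frame with `female_id` (or `individual_id`) and `date`.
#' @param lag integer days after the event forming the window (default 2:4).
#' @return `events` with a `laid` column, dropped events in `attr(,"drops")`.
#' @export
build_lagged_laying_response <- function(laying, events, lag = 2:4) {
  fid <- if ("female_id" %in% names(events)) events$female_id else
    events$individual_id
  if (is.null(fid)) stop("events need a female_id or individual_id column")
  edate <- as.Date(events$date)
  ldate <- as.Date(laying$date)
  lkey <- paste(laying$female_id, as.character(ldate))
  egg <- as.integer(laying$egg_laid)
  ne <- nrow(events)
  # one vectorized lookup for all events x window days
  wkeys <- paste(rep(fid, each = length(lag)),
                 as.character(rep(edate, each = length(lag)) + lag))
  idx <- matrix(match(wkeys, lkey), nrow = length(lag))
  covered <- colSums(is.na(idx)) == 0L
  laid <- rep(NA_integer_, ne)
  if (any(covered)) {
    hit <- matrix(egg[idx[, covered, drop = FALSE]], nrow = length(lag))
    laid[covered] <- as.integer(colSums(hit == 1L) > 0L)
  }
  out <- events[covered, , drop = FALSE]
  out$laid <- laid[covered]
  attr(out, "drops") <- data.frame(
    female_id = fid[!covered], date = as.character(edate[!covered]),
    reason = rep("laying window (days +2 to +4) not covered", sum(!covered)),
    stringsAsFactors = FALSE)
  out
}

#' Filter image events for the selection (egg-laying) analysis
#'
#' Keeps image events on days whose daily maximum air temperature exceeds
#' 20 degrees C, taken after the first 45 days of the breeding season (pair
#' acclimation period), from females that laid at least `min_eggs` eggs in
#' that year; events are labelled by the air temperature at image time as
#' `benign` (20-30 degrees C) or `hot` (at or above 30), and events at or
#' below 20 are dropped. All filters are computed as independent masks on
#' the unfiltered data, so their order of application cannot matter. The
#' lagged laying response is attached via [build_lagged_laying_response()]
#' and the head-neck deviation is standardized over the retained events.
#'
#' @param frame observation data.frame from [build_observations()].
#' @param laying laying records (`female_id, date, egg_laid`).
#' @param weather hourly weather table, used for the daily-maximum screen.
#' @param ages optional data.frame `female_id, year, age_class` with
#'   `age_class` in `"2"`/`">2"`; defaults to `">2"`.
#' @param season_starts optional named vector of season start dates by year
#'   (`"2014" = "2014-09-01"`); default: the first laying date in the
#'   female's enclosure-year.
#' @param burnin_days events within this many days of season start are
#'   removed (default 45).
#' @param min_eggs minimum eggs per female-year (default 10).
#' @param lag laying window (default 2:4).
#' @return Selection frame with columns `female_id`, `date`, `year`,
#'   `enclosure_id`, `subspecies_class`, `period_category`,
#'   `head_neck_dev_std`, `age_class`, `laid`.
#' @export
apply_selection_filters <- function(frame, laying, weather, ages = NULL,
                                    season_starts = NULL, burnin_days = 45,
                                    min_eggs = 10, lag = 2:4) {
  weather <- validate_weather(weather)
  fdate <- as.Date(frame$date)
  fyear <- format(fdate, "%Y")

  # hot-day screen: daily maximum air temperature above 20 C
  dmax <- tapply(weather$air_t, weather$date, max)
  day_ok <- !is.na(dmax[frame$date]) & dmax[frame$date] > 20

  # time-of-image period: benign or hot; cold moments dropped
  period <- ifelse(frame$air_t >= 30, "hot",
                   ifelse(frame$air_t > 20, "benign", NA_character_))

  # season burn-in mask
  ldate <- as.Date(laying$date)
  lyear <- format(ldate, "%Y")
  if (is.null(season_starts)) {
    fem_enc <- tapply(frame$enclosure_id, frame$individual_id,
                      function(z) z[1L])
    lenc <- fem_enc[laying$female_id]
    key <- paste(lenc, lyear)
    ldn <- as.integer(ldate)
    start_by_encyear <- tapply(ldn, key, min)
    start_by_year <- tapply(ldn, lyear, min)
    ekey <- paste(frame$enclosure_id, fyear)
    season_start <- as.Date(
      ifelse(ekey %in% names(start_by_encyear),
             start_by_encyear[ekey], start_by_year[fyear]),
      origin = "1970-01-01")
  } else {
    season_start <- as.Date(season_starts[fyear])
  }
  season_day <- as.integer(fdate - season_start) + 1L
  season_ok <- !is.na(season_day) & season_day > burnin_days

  # productivity mask: >= min_eggs eggs per female-year
  eggs_fy <- tapply(as.integer(laying$egg_laid),
                    paste(laying$female_id, lyear), sum)
  fkey <- paste(frame$individual_id, fyear)
  eggs <- ifelse(fkey %in% names(eggs_fy), eggs_fy[fkey], 0)
  eggs_ok <- eggs >= min_eggs

  keep <- day_ok & !is.na(period) & season_ok & eggs_ok
  if (!any(keep)) stop("no events remain after the selection filters")
  sel <- data.frame(
    female_id = frame$individual_id[keep],
    date = frame$date[keep],
    year = fyear[keep],
    enclosure_id = frame$enclosure_id[keep],
    subspecies_class = frame$subspecies_class[keep],
    air_t = frame$air_t[keep],
    period_category = factor(period[keep], levels = c("benign", "hot")),
    head_neck_dev = frame$head_neck_dev[keep],
    season_day = season_day[keep],
    stringsAsFactors = FALSE)

  sel <- build_lagged_laying_response(laying, sel, lag)
  if (!nrow(sel)) stop("no events remain with a covered laying window")
  sel$head_neck_dev_std <- standardize_covariate(sel$head_neck_dev)

  if (is.null(ages)) {
    sel$age_class <- ">2"
  } else {
    akey <- paste(ages$female_id, ages$year)
    age <- stats::setNames(as.character(ages$age_class), akey)
    sel$age_class <- unname(age[paste(sel$female_id, sel$year)])
    sel$age_class[is.na(sel$age_class)] <- ">2"
  }
  sel$age_class <- factor(sel$age_class, levels = c(">2", "2"))
  sel
}

#' Category model: genetic variation in head thermoregulation
#'
#' Head-neck deviation as a Gaussian response; fixed effects of temperature
#' category, the standardized within-category air-temperature deviation,
#' time of day (linear and quadratic), subspecies and its interaction with
#' category; random effects of year, enclosure and date, a 3 x 3
#' unstructured individual-by-category covariance (permanent environment)
#' and, when a pedigree is supplied, a second pedigree-linked
#' individual-by-category covariance (additive genetic); residual variance
#' estimated separately per category. Feeds [repeatability()],
#' [heritability()], [evolvability()] and [quantgen_summary()].
#'
#' @param observations data.frame from [build_observations()].
#' @param pedigree optional `qg_pedigree` covering all imaged individuals.
#' @return A `qg_recipe`.
#' @export
recipe_headneck_category_model <- function(observations, pedigree = NULL) {
  d <- observations
  d$category <- category_factor(d$category)
  d$subspecies_class <- subspecies_factor(d$subspecies_class)
  d$year <- as.character(d$year)
  base <- "~ category + within_category_dev + time_scaled + time_scaled_sq"
  fixed <- base
  if (length(unique(d$subspecies_class)) > 1L) {
    fixed <- paste(base, "+ subspecies_class")
    # the category x subspecies interaction needs every cell observed
    if (all(table(d$category, d$subspecies_class) > 0L)) {
      fixed <- paste(fixed, "+ category:subspecies_class")
    }
  }
  random <- common_random()
  random$individual <- list(group = "individual_id", design = "cat(category)")
  if (!is.null(pedigree)) {
    random$animal <- list(group = "individual_id", design = "cat(category)",
                          pedigree = TRUE)
  }
  model <- qg_model("head_neck_dev", fixed, "gaussian", random,
                    residual = "by:category", settings = qg_settings())
  new_recipe(model, d, pedigree)
}

#' Joint head and neck surface-temperature model
#'
#' Stacks each image into two rows (head and neck surface temperature) and
#' models the temperature-change reaction norm with a body-part factor
#' interacting with every fixed effect, so the head-vs-neck difference in
#' warming and cooling rates is an explicit contrast. Random effects: year,
#' enclosure, date, image (head and neck of one image share it) and a 3 x 3
#' unstructured individual term over intercept and the two
#' direction-specific slopes.
#'
#' @inheritParams recipe_headneck_category_model
#' @return A `qg_recipe`; the slope contrasts are the
#'   `tc_inc:body_partneck` and `tc_dec:body_partneck` coefficients.
#' @export
recipe_body_part_model <- function(observations) {
  if (!all(c("head_t", "neck_t") %in% names(observations))) {
    stop("observations must carry both head_t and neck_t")
  }
  d <- observations
  long <- rbind(
    transform(d, surface_t = d$head_t, body_part = "head"),
    transform(d, surface_t = d$neck_t, body_part = "neck"))
  long$body_part <- factor(long$body_part, levels = c("head", "neck"))
  long$subspecies_class <- subspecies_factor(long$subspecies_class)
  long$year <- as.character(long$year)
  core <- "tc_dec + tc_inc + time_scaled + time_scaled_sq"
  if (length(unique(long$subspecies_class)) > 1L) {
    core <- paste(core, "+ subspecies_class")
  }
  fixed <- paste0("~ (", core, ") * body_part")
  random <- common_random()
  random$image <- list(group = "image_id", design = "1")
  random$individual <- list(group = "individual_id",
                            design = c("1", "tc_dec", "tc_inc"))
  model <- qg_model("surface_t", fixed, "gaussian", random,
                    residual = "homogeneous", settings = qg_settings())
  new_recipe(model, long)
}

#' Threshold model: head-neck deviation and egg-laying rate
#'
#' Binary-liability (probit) model of the lagged laying response on the
#' standardized head-neck deviation, its interaction with the period
#' category (benign vs hot moment of a hot day), subspecies and an age
#' factor (2 vs older), with year, enclosure, date and female as random
#' effects. The default schedule is the long one used for threshold fits
#' (31.5M iterations, 1.5M burn-in, thinning 10,000).
#'
#' @param selection_frame output of [apply_selection_filters()].
#' @return A `qg_recipe`; see [selection_slopes()] for the period-specific
#'   slopes.
#' @export
recipe_selection_model <- function(selection_frame) {
  d <- selection_frame
  if (abs(mean(d$head_neck_dev_std)) > 1e-6 ||
      abs(stats::sd(d$head_neck_dev_std) - 1) > 1e-6) {
    stop("head_neck_dev_std must be standardized (mean 0, unit variance)")
  }
  d$subspecies_class <- subspecies_factor(d$subspecies_class)
  d$year <- as.character(d$year)
  fixed <- "~ head_neck_dev_std * period_category"
  if (length(unique(d$subspecies_class)) > 1L) {
    fixed <- paste(fixed, "+ subspecies_class")
  }
  if (length(unique(d$age_class)) > 1L) fixed <- paste(fixed, "+ age_class")
  random <- common_random()
  random$individual <- list(group = "female_id", design = "1")
  model <- qg_model("laid", fixed, "threshold", random,
                    residual = "homogeneous",
                    settings = qg_settings(31500000, 1500000, 10000))
  new_recipe(model, d)
}

#' Period-specific selection gradients from a threshold fit
#'
#' @param fit a `qgfit` from [recipe_selection_model()].
#' @return List with per-draw liability-scale slopes `benign` and `hot`.
#' @export
selection_slopes <- function(fit) {
  b <- posterior_draws(fit, "head_neck_dev_std")
  int <- "head_neck_dev_std:period_categoryhot"
  list(benign = b,
       hot = if (int %in% colnames(fit$samples)) b + fit$samples[, int] else b)
}

#' Subspecies reaction-norm model with a genetic slope-intercept structure
#'
#' Random-regression model of the head-neck deviation on standardized
#' temperature change with direction-specific slopes: fixed effects of the
#' reaction norm, subspecies and its interaction with both slopes, and time
#' of day; random effects of year, enclosure, date, a 3 x 3 unstructured
#' individual term over (intercept, decrease slope, increase slope) and its
#' pedigree-linked additive-genetic counterpart. The genetic
#' slope-intercept correlation is available via [genetic_correlation()]
#' on the `"animal"` term.
#'
#' @inheritParams recipe_headneck_category_model
#' @return A `qg_recipe`.
#' @export
recipe_subspecies_reaction_norm <- function(observations, pedigree) {
  d <- observations
  d$subspecies_class <- subspecies_factor(d$subspecies_class)
  d$year <- as.character(d$year)
  fixed <- "~ tc_dec + tc_inc + time_scaled + time_scaled_sq"
  if (length(unique(d$subspecies_class)) > 1L) {
    fixed <- paste(fixed,
                   "+ subspecies_class + subspecies_class:(tc_dec + tc_inc)")
  }
  random <- common_random()
  random$individual <- list(group = "individual_id",
                            design = c("1", "tc_dec", "tc_inc"))
  random$animal <- list(group = "individual_id",
                        design = c("1", "tc_dec", "tc_inc"), pedigree = TRUE)
  model <- qg_model("head_neck_dev", fixed, "gaussian", random,
                    residual = "homogeneous", settings = qg_settings())
  new_recipe(model, d, pedigree)
}
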