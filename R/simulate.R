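# Seeded synthetic-data generator. Defaults emulate the study regime: a
# nine-generation pedigree founded by 139 individuals, ~423 measured females
# averaging ~6.5 thermal images each across 48 study days in six breeding
# seasons, air temperatures with diurnal structure inside [-5, 45] C, a
# head-neck deviation built from reaction-norm fixed effects plus additive
# genetic, permanent-environment, year, enclosure, date and per-category
# residual variance, and daily egg laying driven by a lagged probit effect
# of the head-neck deviation on hot-period days.

#' Simulation configuration with known ground truth
#'
#' @param seed integer seed; mandatory, drives every stochastic stage.
#' @param n_founders founding individuals (generation 0).
#' @param n_generations non-overlapping descendant generations.
#' @param pairs_per_generation breeding pairs formed per generation.
#' @param offspring_per_pair offspring per pair.
#' @param n_measured_females females carrying thermal images.
#' @param images_per_female mean images per measured female.
#' @param years calendar years of the study.
#' @param days_per_year imaging days per year.
#' @param n_enclosures number of enclosures.
#' @param founder_subspecies_prob named founder-label probabilities.
#' @param weather list of diurnal-climate parameters: `mean` daily mean
#'   (degrees C), `day_sd` innovation SD of the day-to-day AR(1) mean,
#'   `amplitude` mean diurnal half-range, `amplitude_sd` its SD.
#' @param fixed list of true fixed effects: `intercept`, `slope_dec`,
#'   `slope_inc` (per unit standardized temperature change), `time`,
#'   `time_sq`, and per-subspecies slope shifts `subspecies_inc`,
#'   `subspecies_dec` (degrees C).
#' @param G,PE 3 x 3 additive-genetic and permanent-environment covariance
#'   matrices over (cold, benign, hot), degrees C squared.
#' @param s2_year,s2_enclosure,s2_date scalar variance components (C^2).
#' @param s2_res length-3 per-category residual variances (C^2).
#' @param laying list: `alpha` (liability intercept), `beta_hn` (liability
#'   effect per SD of hot-period head-neck deviation), `age2_effect`,
#'   `age2_fraction`, `season_length` (days).
#' @return A `sim_config` list; true repeatability and heritability per
#'   category (by the reporting definitions, date variance excluded) are in
#'   `$truth_h2` and `$truth_R`.
#' @export
sim_config <- function(seed,
                       n_founders = 139,
                       n_generations = 8,
                       pairs_per_generation = 24,
                       offspring_per_pair = 4,
                       n_measured_females = 423,
                       images_per_female = 6.5,
                       years = 2012:2017,
                       days_per_year = 8,
                       n_enclosures = 60,
                       founder_subspecies_prob = c(SAB = 0.7, ZB = 0.2, KR = 0.1),
                       weather = list(mean = 20, day_sd = 6, amplitude = 11,
                                      amplitude_sd = 1.5),
                       fixed = list(intercept = 0.3, slope_dec = 1.5,
                                    slope_inc = -2, time = 0.1, time_sq = -0.05,
                                    subspecies_inc = c(SAB = 0, ZB = 0, KR = 1),
                                    subspecies_dec = c(SAB = 0, ZB = 0, KR = 0)),
                       G = cov3(c(0.17, 0.13, 0.17), 0.6),
                       PE = cov3(c(0.33, 0.22, 0.33), 0.6),
                       s2_year = 0.1, s2_enclosure = 0.1, s2_date = 0.1,
                       s2_res = c(1.5, 1.2, 1.5),
                       laying = list(alpha = -0.2, beta_hn = -0.16,
                                     age2_effect = -0.3, age2_fraction = 0.2,
                                     season_length = 130)) {
  if (missing(seed)) stop("a seed is mandatory")
  G <- as.matrix(G); PE <- as.matrix(PE)
  stopifnot(nrow(G) == 3, nrow(PE) == 3, length(s2_res) == 3)
  for (M in list(G, PE)) {
    if (inherits(try(chol(M + diag(1e-12, 3)), silent = TRUE), "try-error")) {
      stop("G and PE must be positive definite")
    }
  }
  cfg <- list(seed = as.integer(seed), n_founders = n_founders,
              n_generations = n_generations,
              pairs_per_generation = pairs_per_generation,
              offspring_per_pair = offspring_per_pair,
              n_measured_females = n_measured_females,
              images_per_female = images_per_female, years = years,
              days_per_year = days_per_year, n_enclosures = n_enclosures,
              founder_subspecies_prob = founder_subspecies_prob,
              weather = weather,
              fixed = fixed, G = G, PE = PE, s2_year = s2_year,
              s2_enclosure = s2_enclosure, s2_date = s2_date,
              s2_res = s2_res, laying = laying)
  denomR <- diag(PE) + s2_year + s2_enclosure + s2_res
  cfg$truth_R <- stats::setNames(diag(PE) / denomR, c("cold", "benign", "hot"))
  cfg$truth_h2 <- stats::setNames(diag(G) / (denomR + diag(G)),
                                  c("cold", "benign", "hot"))
  if (any(cfg$truth_h2 < 0 | cfg$truth_h2 > 1)) stop("derived h2 outside [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Constant-correlation 3 x 3 covariance matrix
#' @param variances length-3 diagonal.
#' @param rho common correlation.
#' @return 3 x 3 covariance matrix.
#' @export
cov3 <- function(variances, rho = 0.6) {
  s <- sqrt(variances)
  R <- matrix(rho, 3, 3); diag(R) <- 1
  R * tcrossprod(s)
}

#' Variance components achieving target heritability and repeatability
#'
#' Solves for the additive and permanent-environment variances that give the
#' requested `h2` and `R` under the reporting definitions (date variance
#' excluded from denominators), holding year + enclosure + residual at
#' `other` total variance split as 0.1/0.1/rest. The default `other` keeps
#' the phenotype on the study's degrees-Celsius scale (within-category
#' residual SD above one degree).
#'
#' @param h2 target heritability per category.
#' @param R target repeatability per category.
#' @param other total of year + enclosure + residual variance (C^2).
#' @param rho cross-category correlation for G and PE.
#' @return List with `G`, `PE`, `s2_year`, `s2_enclosure`, `s2_res`.
#' @export
sim_variances <- function(h2, R, other = 1.7, rho = 0.6) {
  stopifnot(h2 >= 0, h2 < 1, R >= 0, R < 1)
  # denom_R = pe + year + enc + res ; pe = R * denom_R
  denomR <- other / (1 - R)
  pe <- R * denomR
  a <- h2 / (1 - h2) * denomR
  list(G = cov3(rep(a, 3), rho), PE = cov3(rep(pe, 3), rho),
       s2_year = 0.1, s2_enclosure = 0.1,
       s2_res = rep(other - 0.2, 3))
}

#' Simulate a multi-generation pedigree
#'
#' Non-overlapping generations: each generation forms random sire-dam pairs
#' (without selfing, parents drawn from the previous generation) with a
#' fixed number of offspring per pair. Founders carry subspecies labels.
#'
#' @param config a [sim_config()].
#' @return A `qg_pedigree`.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  nf <- config$n_founders
  labels <- sample(names(config$founder_subspecies_prob), nf, replace = TRUE,
                   prob = config$founder_subspecies_prob)
  id <- sprintf("F%03d", seq_len(nf))
  sex <- rep_len(c("M", "F"), nf)
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  subspecies <- labels
  cohort <- rep(0L, nf)
  prev_m <- id[sex == "M"]
  prev_f <- id[sex == "F"]
  for (g in seq_len(config$n_generations)) {
    npairs <- config$pairs_per_generation
    if (length(prev_m) == 0L || length(prev_f) == 0L) {
      stop("infeasible pedigree sizes: generation ", g,
           " has no available sires or dams")
    }
    # parents re-mate across pairs when there are more pairs than candidates
    sires <- sample(prev_m, npairs, replace = npairs > length(prev_m))
    dams <- sample(prev_f, npairs, replace = npairs > length(prev_f))
    noff <- npairs * config$offspring_per_pair
    gid <- sprintf("G%dI%04d", g, seq_len(noff))
    gsex <- sample(rep_len(c("M", "F"), noff))
    id <- c(id, gid)
    sire <- c(sire, rep(sires, each = config$offspring_per_pair))
    dam <- c(dam, rep(dams, each = config$offspring_per_pair))
    subspecies <- c(subspecies, rep(NA_character_, noff))
    cohort <- c(cohort, rep(g, noff))
    sex <- c(sex, gsex)
    prev_m <- gid[gsex == "M"]
    prev_f <- gid[gsex == "F"]
  }
  ped <- pedigree(id, sire, dam, subspecies, cohort)
  attr(ped, "sex") <- stats::setNames(sex, id)[ped$id]
  ped
}

#' Simulate multivariate breeding values along a pedigree
#'
#' Draws one q-vector per individual from the zero-mean matrix-normal with
#' covariance `G` (across traits) and `A` (across individuals), via the
#' Cholesky factors of each: `U = L_A Z L_G'` with `Z` iid standard normal.
#'
#' @param A additive relationship matrix.
#' @param G trait covariance matrix (positive definite).
#' @return Matrix (individuals x traits) of breeding values.
#' @export
simulate_breeding_values <- function(A, G) {
  G <- as.matrix(G)
  LG <- tryCatch(t(chol(G)), error = function(e) stop("G is not positive definite"))
  LA <- tryCatch(t(chol(A)), error = function(e) {
    t(chol(A + diag(1e-10, nrow(A))))
  })
  Z <- matrix(stats::rnorm(nrow(A) * nrow(G)), nrow(A), nrow(G))
  U <- LA %*% Z %*% t(LG)
  rownames(U) <- rownames(A)
  U
}

#' Simulate hourly weather with diurnal structure
#'
#' Imaging days are placed mid-season in each year; each day gets an
#' autocorrelated daily mean and a diurnal sinusoid peaking mid-afternoon,
#' at hourly resolution, clamped to the observed climate range \[-5, 45\] C.
#'
#' @param config a [sim_config()].
#' @return List with `weather` (`date`, `hour`, `air_t`), `study_days`
#'   (character dates) and `season_starts` (named by year).
#' @export
simulate_weather <- function(config) {
  set.seed(config$seed + 1L)
  rows <- list()
  study_days <- character(0)
  season_starts <- stats::setNames(
    as.character(as.Date(paste0(config$years, "-09-01"))),
    as.character(config$years))
  for (yr in config$years) {
    start <- as.Date(paste0(yr, "-09-01"))
    offs <- sort(sample(50:120, config$days_per_year))
    days <- start + offs
    wp <- config$weather
    mu <- wp$mean
    for (d in seq_along(days)) {
      mu <- wp$mean + 0.6 * (mu - wp$mean) + stats::rnorm(1, 0, wp$day_sd)
      amp <- stats::rnorm(1, wp$amplitude, wp$amplitude_sd)
      h <- 0:23
      t <- mu + amp * cos(2 * pi * (h - 14) / 24)  # warmest mid-afternoon
      rows[[length(rows) + 1L]] <- data.frame(
        date = as.character(days[d]), hour = h,
        air_t = round(pmin(45, pmax(-5, t)), 2))
    }
    study_days <- c(study_days, as.character(days))
  }
  list(weather = do.call(rbind, rows), study_days = study_days,
       season_starts = season_starts)
}

#' Simulate a thermal-image dataset with known truth
#'
#' Realizes the observation model: for each measured female and sampled
#' timestamp the head-neck deviation is the reaction-norm fixed part plus
#' the female's category breeding value, category permanent-environment
#' effect, year, enclosure and date effects and a per-category residual.
#' Absolute neck temperatures follow a linear baseline in air temperature
#' and the head temperature is the neck plus the deviation, so
#' [build_observations()] reconstructs the generated deviation exactly.
#'
#' @param ped a `qg_pedigree` from [simulate_pedigree()].
#' @param wx output of [simulate_weather()].
#' @param config a [sim_config()].
#' @return List with `images` (raw image table), `truth` (breeding values,
#'   permanent-environment effects, generating parameters, true per-category
#'   repeatability/heritability, per-image deviations).
#' @export
simulate_thermal_dataset <- function(ped, wx, config) {
  set.seed(config$seed + 2L)
  sexes <- attr(ped, "sex")
  females <- ped$id[!is.na(sexes) & sexes == "F" & !is.na(ped$sire)]
  if (length(females) < config$n_measured_females) {
    females <- ped$id[!is.na(sexes) & sexes == "F"]
  }
  if (length(females) < config$n_measured_females) {
    stop("pedigree has too few females (", length(females), ") for ",
         config$n_measured_females, " measured individuals")
  }
  meas <- sort(sample(females, config$n_measured_females))
  nm <- length(meas)

  A <- amatrix(ped)
  a <- simulate_breeding_values(A, config$G)
  pe <- matrix(stats::rnorm(nm * 3), nm, 3) %*% chol(config$PE)
  rownames(pe) <- meas

  sf <- subspecies_fractions(ped)
  cls <- sf$class[meas]
  frac <- sf$fractions[meas, , drop = FALSE]

  years <- as.character(config$years)
  year_eff <- stats::setNames(stats::rnorm(length(years), 0, sqrt(config$s2_year)),
                              years)
  encl <- sprintf("E%03d", seq_len(config$n_enclosures))
  enc_eff <- stats::setNames(stats::rnorm(length(encl), 0, sqrt(config$s2_enclosure)),
                             encl)
  date_eff <- stats::setNames(
    stats::rnorm(length(wx$study_days), 0, sqrt(config$s2_date)), wx$study_days)
  fem_enc <- stats::setNames(sample(encl, nm, replace = TRUE), meas)

  n_img <- pmax(1L, stats::rpois(nm, config$images_per_female - 1) + 1L)
  rows <- vector("list", nm)
  for (i in seq_len(nm)) {
    k <- n_img[i]
    day <- sample(wx$study_days, k, replace = TRUE)
    hour <- stats::runif(k, 5.5, 17.75)
    rows[[i]] <- data.frame(individual_id = meas[i], date = day, hour = hour,
                            stringsAsFactors = FALSE)
  }
  img <- do.call(rbind, rows)
  img <- img[order(img$date, img$individual_id, img$hour), ]
  ts <- as.POSIXct(paste0(img$date, " 00:00:00"), tz = "UTC") + img$hour * 3600
  img$datetime <- format(ts, "%Y-%m-%dT%H:%M:%S")
  img$year <- as.integer(substr(img$date, 1, 4))
  img$image_id <- sprintf("IMG%05d", seq_len(nrow(img)))

  air_t <- interpolate_air_temperature(wx$weather, ts)
  mad <- max(abs(air_t - 20))
  tc <- temperature_change_transform(air_t, 20, mad)
  cat3 <- assign_temperature_category(air_t)
  ci <- as.integer(cat3)
  time_scaled <- standardize_covariate(img$hour)

  fx <- config$fixed
  # founder labels actually present may be a subset of the named effects
  labs_i <- intersect(colnames(frac), names(fx$subspecies_inc))
  labs_d <- intersect(colnames(frac), names(fx$subspecies_dec))
  fidx <- match(img$individual_id, rownames(frac))
  sub_inc <- as.numeric(frac[fidx, labs_i, drop = FALSE] %*%
                          fx$subspecies_inc[labs_i])
  sub_dec <- as.numeric(frac[fidx, labs_d, drop = FALSE] %*%
                          fx$subspecies_dec[labs_d])
  tcd <- tc$temp_change * (tc$direction == "decrease")
  tci <- tc$temp_change * (tc$direction == "increase")
  fixed_part <- fx$intercept + fx$slope_dec * tcd + fx$slope_inc * tci +
    sub_dec * tcd + sub_inc * tci +
    fx$time * time_scaled + fx$time_sq * time_scaled^2
  dev <- fixed_part +
    a[cbind(match(img$individual_id, rownames(a)), ci)] +
    pe[cbind(match(img$individual_id, rownames(pe)), ci)] +
    year_eff[as.character(img$year)] +
    enc_eff[fem_enc[img$individual_id]] +
    date_eff[img$date] +
    stats::rnorm(nrow(img), 0, sqrt(config$s2_res)[ci])

  neck_t <- 28 + 0.35 * air_t
  images <- data.frame(
    image_id = img$image_id, individual_id = img$individual_id,
    datetime = img$datetime,
    head_t = neck_t + dev, neck_t = neck_t,
    head_pixels = 900L, neck_pixels = 1600L,
    enclosure = unname(fem_enc[img$individual_id]), year = img$year,
    subspecies_class = unname(cls[img$individual_id]),
    stringsAsFactors = FALSE)

  truth <- list(a = a, pe = pe, measured = meas, fem_enclosure = fem_enc,
                year_eff = year_eff, enc_eff = enc_eff, date_eff = date_eff,
                subspecies_class = cls, config = config,
                truth_R = config$truth_R, truth_h2 = config$truth_h2,
                head_neck_dev = stats::setNames(dev, img$image_id),
                air_t = stats::setNames(air_t, img$image_id),
                max_abs_dev = mad)
  list(images = images, truth = truth)
}

#' Simulate daily egg-laying records with a lagged thermal effect
#'
#' Each measured female lays daily with probit probability
#' `Phi(alpha + age + beta_hn * x)`, where `x` is the mean standardized
#' hot-period head-neck deviation of her images 2-4 days earlier (zero when
#' none): laying responds to heat-period thermoregulation with the oviduct
#' transit lag. Records cover the full breeding season of every year in
#' which the female was imaged.
#'
#' @param thermal output of [simulate_thermal_dataset()].
#' @param wx output of [simulate_weather()].
#' @param config a [sim_config()].
#' @return List with `laying` (`female_id, date, egg_laid`) and `ages`
#'   (`female_id, year, age_class`).
#' @export
simulate_laying <- function(thermal, wx, config) {
  set.seed(config$seed + 3L)
  lp <- config$laying
  truth <- thermal$truth
  meas <- truth$measured
  age2 <- stats::setNames(
    stats::runif(length(meas)) < lp$age2_fraction, meas)

  # standardized hot-period deviations per image
  imgs <- thermal$images
  air_t <- truth$air_t[imgs$image_id]
  hot <- air_t >= 30
  x_img <- rep(NA_real_, nrow(imgs))
  if (sum(hot) >= 2L) {
    x_img[hot] <- standardize_covariate(truth$head_neck_dev[imgs$image_id][hot])
  }
  idate <- as.Date(imgs$date)

  L <- lp$season_length
  femyear <- unique(imgs[, c("individual_id", "year")])
  nfy <- nrow(femyear)
  # season-day date labels computed once per year
  daychr <- lapply(stats::setNames(nm = names(wx$season_starts)), function(y) {
    as.character(as.Date(wx$season_starts[[y]]) + seq_len(L) - 1L)
  })
  startnum <- vapply(wx$season_starts, function(d) as.integer(as.Date(d)), 0L)
  laid_all <- integer(nfy * L)
  for (k in seq_len(nfy)) {
    f <- femyear$individual_id[k]
    yr <- as.character(femyear$year[k])
    sel <- which(imgs$individual_id == f & !is.na(x_img))
    eta <- rep(lp$alpha + if (age2[f]) lp$age2_effect else 0, L)
    if (length(sel)) {
      # each image pushes its effect onto season days +2..+4 after it
      s <- numeric(L); cnt <- numeric(L)
      off <- as.integer(idate[sel]) - startnum[[yr]] + 1L  # image season day
      for (j in seq_along(sel)) {
        rng <- (off[j] + 2L):(off[j] + 4L)
        rng <- rng[rng >= 1L & rng <= L]
        s[rng] <- s[rng] + x_img[sel[j]]
        cnt[rng] <- cnt[rng] + 1
      }
      hitd <- cnt > 0
      eta[hitd] <- eta[hitd] + lp$beta_hn * s[hitd] / cnt[hitd]
    }
    laid_all[(k - 1L) * L + seq_len(L)] <-
      as.integer(stats::runif(L) < stats::pnorm(eta))
  }
  laying <- data.frame(
    female_id = rep(femyear$individual_id, each = L),
    date = unlist(daychr[as.character(femyear$year)], use.names = FALSE),
    egg_laid = laid_all, stringsAsFactors = FALSE)
  ages <- data.frame(female_id = femyear$individual_id,
                     year = as.character(femyear$year),
                     age_class = ifelse(age2[femyear$individual_id], "2", ">2"),
                     stringsAsFactors = FALSE)
  list(laying = laying, ages = ages)
}

#' Run the full synthetic-study generator
#'
#' @param config a [sim_config()].
#' @return List with `pedigree`, `weather`, `study_days`, `season_starts`,
#'   `images`, `laying`, `ages` and `truth`.
#' @export
simulate_study <- function(config) {
  ped <- simulate_pedigree(config)
  wx <- simulate_weather(config)
  th <- simulate_thermal_dataset(ped, wx, config)
  lay <- simulate_laying(th, wx, config)
  list(pedigree = ped, weather = wx$weather, study_days = wx$study_days,
       season_starts = wx$season_starts, images = th$images,
       laying = lay$laying, ages = lay$ages, truth = th$truth)
}

#' Write a simulated study bundle as CSV files
#'
#' Emits the exact CSV dialects consumed by the loaders: `images.csv`,
#' `weather.csv`, `pedigree.csv`, `laying.csv`, `ages.csv`, plus the
#' generating parameters in `truth.yaml`.
#'
#' @param bundle output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation_csv <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$images, file.path(dir, "images.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$weather, file.path(dir, "weather.csv"),
                   row.names = FALSE, quote = FALSE)
  write_pedigree_csv(bundle$pedigree, file.path(dir, "pedigree.csv"))
  utils::write.csv(bundle$laying, file.path(dir, "laying.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(bundle$ages, file.path(dir, "ages.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- bundle$truth$config
  yaml::write_yaml(list(
    seed = cfg$seed, truth_R = as.list(cfg$truth_R),
    truth_h2 = as.list(cfg$truth_h2),
    s2_year = cfg$s2_year, s2_enclosure = cfg$s2_enclosure,
    s2_date = cfg$s2_date, s2_res = as.list(cfg$s2_res),
    G_diag = as.list(diag(cfg$G)), PE_diag = as.list(diag(cfg$PE))),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
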