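small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_founders = 20, n_generations = 2,
         pairs_per_generation = 8, offspring_per_pair = 3,
         n_measured_females = 15, images_per_female = 5,
         years = 2014:2015, days_per_year = 6, n_enclosures = 6),
    list(...))
  do.call(sim_config, args)
}

test_that("pedigree simulation is deterministic with the expected counts", {
  cfg <- small_cfg(3)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(p1), 20 + 2 * 8 * 3)  # founders + gens x pairs x offspring
  # founders only: identity relationship matrix
  cfg0 <- sim_config(seed = 2, n_founders = 10, n_generations = 0)
  p0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(p0), 10)
  expect_equal(amatrix(p0), diag(10), ignore_attr = TRUE)
})

test_that("breeding values follow the matrix-normal with pedigree covariance", {
  # G near zero gives near-zero values
  A <- diag(50)
  dimnames(A) <- list(paste0("i", 1:50), paste0("i", 1:50))
  set.seed(1)
  u0 <- simulate_breeding_values(A, diag(3) * 1e-12)
  expect_lt(max(abs(u0)), 1e-4)

  # unrelated individuals: empirical variances near G's diagonal
  A2 <- diag(5000)
  dimnames(A2) <- list(paste0("i", 1:5000), paste0("i", 1:5000))
  G <- diag(c(1, 2, 0.5))
  set.seed(2)
  u <- simulate_breeding_values(A2, G)
  expect_lt(max(abs(apply(u, 2, var) / diag(G) - 1)), 0.07)

  # parent-offspring regression slope near one half
  n <- 1000
  id <- c(paste0("s", 1:n), paste0("d", 1:n), paste0("o", 1:n))
  ped <- pedigree(id, c(rep(NA, 2 * n), paste0("s", 1:n)),
                  c(rep(NA, 2 * n), paste0("d", 1:n)))
  A3 <- amatrix(ped)
  set.seed(3)
  u3 <- simulate_breeding_values(A3, diag(1))
  mid <- (u3[paste0("s", 1:n), 1] + u3[paste0("d", 1:n), 1]) / 2
  off <- u3[paste0("o", 1:n), 1]
  # offspring on single parent: expected slope 0.5
  slope <- coef(lm(off ~ u3[paste0("s", 1:n), 1]))[2]
  expect_lt(abs(slope - 0.5), 0.09)
  expect_gt(cor(mid, off), 0.6)

  expect_error(simulate_breeding_values(A, matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("simulated weather respects the climate envelope deterministically", {
  cfg <- small_cfg(4)
  w1 <- simulate_weather(cfg)
  w2 <- simulate_weather(cfg)
  expect_identical(w1$weather, w2$weather)
  expect_gte(min(w1$weather$air_t), -5)
  expect_lte(max(w1$weather$air_t), 45)
  expect_equal(length(w1$study_days), 2 * 6)
  # zero amplitude and day noise: a constant series
  cfgc <- small_cfg(5, weather = list(mean = 20, day_sd = 0, amplitude = 0,
                                      amplitude_sd = 0))
  wc <- simulate_weather(cfgc)
  expect_equal(unique(wc$weather$air_t), 20)
})

test_that("the thermal dataset realizes the observation model exactly", {
  # all variances zero: deviation equals the fixed part
  cfg0 <- small_cfg(6, G = diag(1e-12, 3), PE = diag(1e-12, 3),
                    s2_year = 0, s2_enclosure = 0, s2_date = 0,
                    s2_res = c(0, 0, 0) + 1e-12)
  ped <- simulate_pedigree(cfg0)
  wx <- simulate_weather(cfg0)
  th <- simulate_thermal_dataset(ped, wx, cfg0)
  obs <- build_observations(th$images, wx$weather)
  fx <- cfg0$fixed
  sub <- subspecies_fractions(ped)$fractions[obs$individual_id, , drop = FALSE]
  expected <- fx$intercept + fx$slope_dec * obs$tc_dec +
    fx$slope_inc * obs$tc_inc +
    as.numeric(sub[, names(fx$subspecies_inc), drop = FALSE] %*%
                 fx$subspecies_inc) * obs$tc_inc +
    fx$time * obs$time_scaled + fx$time_sq * obs$time_scaled^2
  expect_lt(max(abs(obs$head_neck_dev - expected)), 1e-4)

  # preprocessing reconstructs the generated deviation to numerical zero
  cfg <- small_cfg(7)
  ped <- simulate_pedigree(cfg)
  wx <- simulate_weather(cfg)
  th <- simulate_thermal_dataset(ped, wx, cfg)
  obs <- build_observations(th$images, wx$weather)
  expect_equal(nrow(obs), nrow(th$images))
  expect_lt(max(abs(obs$head_neck_dev - th$truth$head_neck_dev[obs$image_id])),
            1e-9)
})

test_that("generated data satisfy the upstream type invariants", {
  for (seed in 1:3) {
    cfg <- small_cfg(seed)
    bun <- simulate_study(cfg)
    expect_true(all(bun$images$head_t > -10 & bun$images$head_t < 60))
    hrs <- as.numeric(substr(bun$images$datetime, 12, 13))
    expect_true(all(hrs >= 5 & hrs <= 18))
    expect_true(all(bun$weather$air_t >= -20 & bun$weather$air_t <= 55))
    expect_true(all(bun$laying$egg_laid %in% 0:1))
    expect_true(all(table(paste(bun$laying$female_id, bun$laying$date)) == 1))
    expect_true(all(bun$truth$truth_h2 >= 0 & bun$truth$truth_h2 <= 1))
  }
})

test_that("laying rates follow the probit intercept when the thermal effect is off", {
  cfg <- small_cfg(8, n_measured_females = 30, images_per_female = 3,
                   laying = list(alpha = -0.2, beta_hn = 0, age2_effect = 0,
                                 age2_fraction = 0, season_length = 120))
  bun <- simulate_study(cfg)
  expect_lt(abs(mean(bun$laying$egg_laid) - pnorm(-0.2)), 0.03)
  # deterministic under the seed
  bun2 <- simulate_study(cfg)
  expect_identical(bun$laying, bun2$laying)

  # a hopeless intercept leaves nothing after the productivity screen
  cfg0 <- small_cfg(9, laying = list(alpha = -4, beta_hn = 0, age2_effect = 0,
                                     age2_fraction = 0, season_length = 120))
  bun0 <- simulate_study(cfg0)
  obs0 <- build_observations(bun0$images, bun0$weather)
  expect_error(apply_selection_filters(obs0, bun0$laying, bun0$weather),
               "no events")
})

test_that("target heritability and repeatability solve back from sim_variances", {
  v <- sim_variances(0.07, 0.15)
  cfg <- small_cfg(10, G = v$G, PE = v$PE, s2_year = v$s2_year,
                   s2_enclosure = v$s2_enclosure, s2_res = v$s2_res)
  expect_equal(unname(cfg$truth_h2), rep(0.07, 3), tolerance = 1e-10)
  expect_equal(unname(cfg$truth_R), rep(0.15, 3), tolerance = 1e-10)
})
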