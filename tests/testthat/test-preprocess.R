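test_that("air-temperature spline interpolates hourly records exactly", {
  # a linear ramp is reproduced exactly by a natural cubic spline
  w <- data.frame(date = "2014-11-02", hour = 8:18,
                  air_t = seq(10, 20, length.out = 11))
  ts <- as.POSIXct("2014-11-02 13:00:00", tz = "UTC")
  expect_equal(interpolate_air_temperature(w, ts), 15)
  # midpoint between knots on the ramp
  ts2 <- as.POSIXct("2014-11-02 13:30:00", tz = "UTC")
  expect_equal(interpolate_air_temperature(w, ts2), 15.5)

  # passes through an arbitrary knot value exactly
  w2 <- data.frame(date = "2014-11-02", hour = c(6, 9, 12, 15, 18),
                   air_t = c(12.1, 23.4, 31.8, 29.9, 21.5))
  expect_equal(interpolate_air_temperature(
    w2, as.POSIXct("2014-11-02 09:00:00", tz = "UTC")), 23.4)

  # sinusoidal day: agrees with an independent natural-spline implementation
  h <- 0:23
  y <- 22 + 10 * sin(2 * pi * (h - 8) / 24)
  w3 <- data.frame(date = "2015-01-05", hour = h, air_t = y)
  hq <- c(5.35, 9.5, 13.77, 16.2)
  got <- interpolate_air_temperature(
    w3, as.POSIXct("2015-01-05 00:00:00", tz = "UTC") + hq * 3600)
  expect_equal(got, natural_spline_oracle(h, y, hq), tolerance = 1e-6)

  expect_error(interpolate_air_temperature(
    w, as.POSIXct("2014-11-03 12:00:00", tz = "UTC")), "no weather")
  expect_error(interpolate_air_temperature(
    w, as.POSIXct("2014-11-02 19:30:00", tz = "UTC")), "outside covered")
  w4 <- data.frame(date = "2014-11-02", hour = c(8, 9, 10), air_t = 1:3)
  expect_error(interpolate_air_temperature(
    w4, as.POSIXct("2014-11-02 09:00:00", tz = "UTC")), "fewer than 4")
})

test_that("head-neck deviation is head minus neck", {
  expect_equal(head_neck_deviation(36.2, 37.4), -1.2)
  expect_equal(head_neck_deviation(30, 30), 0)
  expect_equal(head_neck_deviation(40, 36.5), 3.5)
})

test_that("temperature change is normalized absolute deviation from 20 C", {
  r <- temperature_change_transform(c(20, 45, 10), max_abs_dev = 25)
  expect_equal(r$temp_change, c(0, 1, 0.4))
  expect_equal(as.character(r$direction), c("decrease", "increase", "decrease"))
  expect_error(temperature_change_transform(50, max_abs_dev = 25), "stale")
  # monotone in |air_t - 20|
  a <- sort(abs(runif(50, -25, 25)))
  up <- temperature_change_transform(20 + a, max_abs_dev = 25)$temp_change
  expect_true(all(diff(up) >= 0))
})

test_that("temperature categories split at 20 and 30 degrees", {
  expect_equal(as.character(assign_temperature_category(c(20, 29.99, 30, 25, 5))),
               c("cold", "benign", "hot", "benign", "cold"))
})

test_that("covariate standardization gives mean zero unit variance per group", {
  expect_equal(standardize_covariate(1:3), c(-1, 0, 1))
  g <- rep(c("a", "b"), each = 2)
  out <- standardize_covariate(c(10, 20, 1, 5), g)
  expect_equal(out, c(-1, 1, -1, 1) / sqrt(2))
  expect_error(standardize_covariate(c(5, 5, 5)), "constant")
  set.seed(1)
  x <- rnorm(100)
  gg <- sample(letters[1:3], 100, TRUE)
  z <- standardize_covariate(x, gg)
  for (l in letters[1:3]) {
    expect_lt(abs(mean(z[gg == l])), 1e-10)
    expect_lt(abs(sd(z[gg == l]) - 1), 1e-10)
  }
})

test_that("observation building drops invalid rows with reasons and partitions categories", {
  w <- data.frame(date = "2014-11-02", hour = 5:18,
                  air_t = seq(12, 38, length.out = 14))
  img <- data.frame(
    image_id = c("i1", "i2", "i3", "i4", "i5"),
    individual_id = c("f1", "f2", "f3", "", "f5"),
    datetime = c("2014-11-02T08:30:00", "2014-11-02T12:00:00",
                 "2014-11-02T16:45:00", "2014-11-02T10:00:00",
                 "2014-11-02T03:30:00"),
    head_t = c(33, 99, 35, 34, 33), neck_t = c(34, 36, 36.5, 35, 34),
    enclosure = "E1", year = 2014L, stringsAsFactors = FALSE)
  obs <- build_observations(img, w)
  expect_equal(nrow(obs), 2L)
  drops <- attr(obs, "drops")
  expect_setequal(drops$image_id, c("i2", "i4", "i5"))
  expect_match(drops$reason[drops$image_id == "i2"], "head_t")
  expect_match(drops$reason[drops$image_id == "i4"], "individual_id")
  expect_match(drops$reason[drops$image_id == "i5"], "time of day")
  expect_true(all(obs$temp_change >= 0 & obs$temp_change <= 1))
  expect_equal(sum(table(obs$category)), nrow(obs))
  expect_error(build_observations(img[4, ], w), "no valid images")
})
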