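# Sampler correctness against closed-form oracles at small scale. The
# heavier conjugate/recovery/calibration checks live in test-acceptance.R.

test_that("with fixed effects only the posterior mean matches least squares", {
  set.seed(31)
  n <- 150
  x1 <- rnorm(n)
  x2 <- runif(n)
  y <- 1.5 - 2 * x1 + 0.7 * x2 + rnorm(n, 0, 0.05)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  fit <- qgfit(qg_model("y", "~ x1 + x2"), d,
               settings = qg_settings(3000, 500, 2), seed = 11)
  ols <- coef(lm(y ~ x1 + x2, d))
  expect_lt(max(abs(coef(fit) - ols)), 0.01)
  # residuals/fitted are consistent with the data
  expect_equal(fitted(fit) + residuals(fit), d$y)
  expect_lt(max(abs(residuals(fit))), 0.3)
})

test_that("identical seeds give bit-identical draws, different seeds do not", {
  set.seed(5)
  d <- data.frame(y = rnorm(60), g = rep(letters[1:12], 5))
  m <- qg_model("y", "~ 1",
                random = list(g = list(group = "g", design = "1")))
  f1 <- qgfit(m, d, settings = qg_settings(500, 100, 2), seed = 99)
  f2 <- qgfit(m, d, settings = qg_settings(500, 100, 2), seed = 99)
  f3 <- qgfit(m, d, settings = qg_settings(500, 100, 2), seed = 100)
  expect_identical(f1$samples, f2$samples)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("a single random-intercept variance is recovered", {
  set.seed(8)
  ng <- 150; per <- 6
  g <- rep(sprintf("g%03d", 1:ng), each = per)
  u <- rnorm(ng, 0, 1)
  d <- data.frame(y = u[match(g, unique(g))] + rnorm(ng * per, 0, 1), g = g)
  m <- qg_model("y", "~ 1",
                random = list(g = list(group = "g", design = "1")))
  fit <- qgfit(m, d, settings = qg_settings(6000, 1000, 5), seed = 21)
  vg <- fit$samples[, "g.var"]
  expect_lt(abs(mean(vg) - var(u)), 0.3)  # anchored to the realized variance
  expect_lt(abs(mean(fit$samples[, "R.units"]) - 1), 0.2)
  # posterior-mean group effects track the simulated ones
  expect_gt(cor(fit$u_mean$g[, 1], u), 0.7)
})

test_that("non-positive-definite prior scale matrices are rejected", {
  d <- data.frame(y = rnorm(30), g = rep(letters[1:6], 5))
  m <- qg_model("y", "~ 1",
                random = list(g = list(group = "g", design = "1")))
  expect_error(
    qgfit(m, d, prior = list(g = list(V = matrix(-1, 1, 1), nu = 1)),
          settings = qg_settings(200, 50, 1), seed = 1),
    "positive definite")
  expect_error(
    qgfit(m, d, prior = list(g = list(V = diag(1), nu = -2)),
          settings = qg_settings(200, 50, 1), seed = 1),
    "nu")
})

test_that("threshold intercept maps through the probit to the observed rate", {
  set.seed(12)
  d <- data.frame(y = rep(c(0L, 1L), c(150, 350)))
  fit <- qgfit(qg_model("y", "~ 1", family = "threshold"), d,
               settings = qg_settings(6000, 1000, 5), seed = 17)
  expect_lt(abs(pnorm(mean(fit$samples[, "(Intercept)"])) - 0.7), 0.04)
  expect_error(residuals(fit), "threshold")
})

test_that("threshold slope recovers a known liability effect", {
  set.seed(77)
  n <- 600
  x <- rnorm(n)
  y <- as.integer(runif(n) < pnorm(0.3 + 0.8 * x))
  fit <- qgfit(qg_model("y", "~ x", family = "threshold"),
               data.frame(y = y, x = x),
               settings = qg_settings(8000, 2000, 5), seed = 3)
  glmfit <- glm(y ~ x, family = binomial(link = "probit"))
  expect_lt(abs(mean(fit$samples[, "x"]) - coef(glmfit)[["x"]]), 0.1)
})

test_that("unstructured covariance draws are positive definite", {
  set.seed(6)
  obs <- tiny_observations(120, seed = 6)
  m <- qg_model("head_neck_dev", "~ 1", random = list(
    individual = list(group = "individual_id", design = "cat(category)")))
  fit <- qgfit(m, obs, settings = qg_settings(1500, 300, 3), seed = 2)
  for (k in seq_len(nrow(fit$samples))) {
    S <- matrix(0, 3, 3)
    S[lower.tri(S, diag = TRUE)] <- fit$samples[k, grep("^individual\\.",
                                                        colnames(fit$samples))]
    S <- S + t(S) - diag(diag(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_true(all(fit$samples[, "R.units"] > 0))
})

test_that("convergence diagnostics flag divergent chains and pass identical ones", {
  set.seed(9)
  base <- matrix(rnorm(2000), 500, 4,
                 dimnames = list(NULL, paste0("p", 1:4)))
  expect_true(all(convergence_check(list(base, base))$psrf == 1))
  # white noise has negligible lag-1 autocorrelation
  cc <- convergence_check(list(base, base + 0))
  expect_true(all(abs(cc$lag1_autocorr) < 3 / sqrt(500)))
  shifted <- base
  shifted[, 2] <- shifted[, 2] + 5
  cc2 <- convergence_check(list(base, shifted))
  expect_true(cc2$flagged[cc2$parameter == "p2"])
  expect_error(convergence_check(list(base, base[, 1:2])), "mismatched")
})
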