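#' Posterior mode by kernel density estimation
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth (`bw = "nrd0"`),
#' maximized on a dense grid.
#'
#' @param draws numeric vector of posterior draws.
#' @return The abscissa of the density maximum.
#' @export
posterior_mode <- function(draws) {
  stopifnot(length(draws) >= 2L)
  if (stats::sd(draws) == 0) return(draws[1L])
  d <- stats::density(draws, bw = "nrd0", n = 2048L)
  d$x[which.max(d$y)]
}

#' Highest-posterior-density interval
#'
#' The shortest interval containing a fraction `prob` of the draws
#' (empirical HPD: minimal-width window over the sorted sample).
#'
#' @param draws numeric vector of posterior draws.
#' @param prob coverage probability (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  widths <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Two-sided MCMC sign probability
#'
#' `2 * min(#draws > 0, #draws < 0) / N`, floored at `2/N`: the posterior
#' probability that the quantity differs in sign from its point summary.
#'
#' @param draws numeric vector of posterior draws.
#' @return A probability in `[2/N, 1]`.
#' @export
pmcmc <- function(draws) {
  n <- length(draws)
  max(2 * min(sum(draws > 0), sum(draws < 0)) / n, 2 / n)
}

#' Summarize one posterior parameter
#'
#' @param fit a `qgfit` object, or a draws matrix with named columns.
#' @param parameter parameter (column) name.
#' @param prob HPD coverage.
#' @return List with `mode`, `mean`, `hpd_low`, `hpd_high`, `pmcmc`.
#' @export
summarize_posterior <- function(fit, parameter, prob = 0.95) {
  draws <- posterior_draws(fit, parameter)
  hpd <- hpd_interval(draws, prob)
  list(mode = posterior_mode(draws), mean = mean(draws),
       hpd_low = hpd[1L], hpd_high = hpd[2L], pmcmc = pmcmc(draws))
}

#' Extract posterior draws for one parameter
#' @inheritParams summarize_posterior
#' @return Numeric vector of retained draws.
#' @export
posterior_draws <- function(fit, parameter) {
  m <- if (inherits(fit, "qgfit")) fit$samples else as.matrix(fit)
  if (!parameter %in% colnames(m)) {
    stop("unknown parameter '", parameter, "'; available: ",
         paste(utils::head(colnames(m), 12L), collapse = ", "),
         if (ncol(m) > 12L) ", ..." else "")
  }
  m[, parameter]
}

#' Convergence diagnostics across chains
#'
#' Per-parameter lag-1 autocorrelation of the retained draws and the
#' potential scale reduction factor (PSRF) across chains (floored at 1).
#' Parameters with autocorrelation above `ac_limit` or PSRF above
#' `psrf_limit` are flagged.
#'
#' @param chains list of `qgfit` objects (or draws matrices) with identical
#'   parameterization; at least 2 for the PSRF.
#' @param ac_limit,psrf_limit flag thresholds (defaults 0.1 and 1.1).
#' @return data.frame with columns `parameter`, `lag1_autocorr`, `psrf`,
#'   `flagged`.
#' @export
convergence_check <- function(chains, ac_limit = 0.1, psrf_limit = 1.1) {
  stopifnot(length(chains) >= 2L)
  mats <- lapply(chains, function(f) {
    if (inherits(f, "qgfit")) f$samples else as.matrix(f)
  })
  pn <- colnames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(colnames(m), pn) || nrow(m) != nrow(mats[[1L]])) {
      stop("chains have mismatched parameters or lengths")
    }
  }
  ndr <- nrow(mats[[1L]])
  nch <- length(mats)
  lag1 <- vapply(pn, function(p) {
    mean(vapply(mats, function(m) {
      x <- m[, p]
      if (stats::sd(x) == 0) return(0)
      stats::acf(x, lag.max = 1L, plot = FALSE)$acf[2L]
    }, 0))
  }, 0)
  psrf <- vapply(pn, function(p) {
    xs <- vapply(mats, function(m) m[, p], numeric(ndr))
    W <- mean(apply(xs, 2L, stats::var))
    if (W == 0) return(1)
    B_over_n <- stats::var(colMeans(xs))
    vhat <- (ndr - 1) / ndr * W + (1 + 1 / nch) * B_over_n
    sqrt(max(1, vhat / W))
  }, 0)
  data.frame(parameter = pn, lag1_autocorr = unname(lag1),
             psrf = unname(psrf),
             flagged = unname(lag1 > ac_limit | psrf > psrf_limit),
             row.names = NULL, stringsAsFactors = FALSE)
}
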