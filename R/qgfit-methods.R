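#' @export
#' @method print qgfit
print.qgfit <- function(x, ...) {
  cat("Bayesian mixed model (", x$family, "), n = ", x$n,
      ", retained draws = ", x$nsave, "\n", sep = "")
  cat("Schedule: nitt =", format(x$settings$nitt, big.mark = ","),
      "burn-in =", format(x$settings$burnin, big.mark = ","),
      "thin =", x$settings$thin, "| seed =", x$seed, "\n")
  if (x$p > 0L) {
    cat("Fixed effects:", paste(x$fixed_names, collapse = ", "), "\n")
  }
  for (t in x$terms) {
    cat("Random term:", t$name, "(q =", t$q, ", levels =", t$nlev,
        if (t$pedigree) ", pedigree-linked)" else ")", "\n")
  }
  invisible(x)
}

#' Posterior summary table for a fitted model
#'
#' One row per parameter: posterior mean, kernel-density mode, 95% HPD
#' interval, and the two-sided sign probability `pMCMC` (reported for fixed
#' effects only, as variances cannot change sign).
#'
#' @param object a `qgfit`.
#' @param prob HPD coverage.
#' @param ... unused.
#' @return data.frame, one row per parameter.
#' @export
#' @method summary qgfit
summary.qgfit <- function(object, prob = 0.95, ...) {
  s <- object$samples
  out <- do.call(rbind, lapply(colnames(s), function(p) {
    d <- s[, p]
    hpd <- hpd_interval(d, prob)
    data.frame(parameter = p, post_mean = mean(d),
               post_mode = posterior_mode(d),
               hpd_low = hpd[1L], hpd_high = hpd[2L],
               pmcmc = if (p %in% object$fixed_names) pmcmc(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("summary.qgfit", "data.frame")
  out
}

#' @export
#' @method print summary.qgfit
print.summary.qgfit <- function(x, digits = 3, ...) {
  y <- x
  for (cn in c("post_mean", "post_mode", "hpd_low", "hpd_high", "pmcmc")) {
    y[[cn]] <- signif(y[[cn]], digits)
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method coef qgfit
coef.qgfit <- function(object, ...) {
  if (object$p == 0L) return(numeric(0))
  stats::setNames(colMeans(object$samples[, object$fixed_names, drop = FALSE]),
                  object$fixed_names)
}

#' @export
#' @method fitted qgfit
fitted.qgfit <- function(object, ...) object$fitted

#' @export
#' @method residuals qgfit
residuals.qgfit <- function(object, ...) {
  if (object$family == "threshold") {
    stop("residuals are not defined for the threshold family; ",
         "the response is a latent liability")
  }
  object$response - object$fitted
}

#' Trace plots of retained draws
#'
#' @param x a `qgfit`.
#' @param parameters parameter names (default: first 6).
#' @param ... passed to [graphics::plot()].
#' @export
#' @method plot qgfit
plot.qgfit <- function(x, parameters = NULL, ...) {
  if (is.null(parameters)) {
    parameters <- utils::head(colnames(x$samples), 6L)
  }
  old <- graphics::par(mfrow = c(length(parameters), 1L),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in parameters) {
    graphics::plot(x$samples[, p], type = "l", ylab = p, xlab = "", ...)
  }
  invisible(x)
}
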