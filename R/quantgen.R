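#' Per-draw variance-component extraction
#'
#' Pulls the named variance column of a random term (the `cat:cat` diagonal
#' for category-structured terms, the plain variance for scalar terms) out
#' of a fitted model's retained draws.
#'
#' @param fit a `qgfit` or a named draws matrix.
#' @param term random-term name (e.g. `"individual"`, `"animal"`, `"year"`).
#' @param category optional category label for q x q terms.
#' @return Numeric vector of per-draw variances.
#' @export
vc_draws <- function(fit, term, category = NULL) {
  m <- if (inherits(fit, "qgfit")) fit$samples else as.matrix(fit)
  nm <- if (is.null(category)) paste0(term, ".var") else
    paste0(term, ".", category, ":", category)
  if (!nm %in% colnames(m)) {
    stop("variance component '", nm, "' not present in the samples")
  }
  m[, nm]
}

ratio_components <- function(fit, category, pe_term, include_date) {
  m <- if (inherits(fit, "qgfit")) fit$samples else as.matrix(fit)
  res_nm <- if (paste0("R.", category) %in% colnames(m)) {
    paste0("R.", category)
  } else "R.units"
  comps <- list(pe = vc_draws(m, pe_term, category),
                year = vc_draws(m, "year"),
                enclosure = vc_draws(m, "enclosure"),
                res = posterior_draws(m, res_nm))
  # the date variance is estimated but deliberately left out of the
  # denominator by default (the published ratio definitions)
  if (include_date) comps$date <- vc_draws(m, "date")
  comps
}

#' Repeatability of the head-neck deviation per temperature category
#'
#' Per retained draw,
#' `R = s2_pe / (s2_pe + s2_year + s2_enclosure + s2_res)`, with the
#' permanent-environment and residual variances taken for the requested
#' category. The date variance is excluded from the denominator by default;
#' set `include_date = TRUE` to add it.
#'
#' @param fit a `qgfit` from the category model (or a named draws matrix).
#' @param category category label (`"cold"`, `"benign"`, `"hot"`), or `NULL`
#'   for a scalar individual term.
#' @param pe_term name of the permanent-environment term.
#' @param include_date include the date variance in the denominator?
#' @return Numeric vector of per-draw repeatabilities in `[0, 1]`.
#' @export
repeatability <- function(fit, category = NULL, pe_term = "individual",
                          include_date = FALSE) {
  cp <- ratio_components(fit, category, pe_term, include_date)
  denom <- Reduce(`+`, cp)
  cp$pe / denom
}

#' Narrow-sense heritability per temperature category
#'
#' Per retained draw,
#' `h2 = s2_a / (s2_pe + s2_a + s2_year + s2_enclosure + s2_res)`; the
#' additive-genetic variance comes from the pedigree-linked term. Errors
#' when the fit contains no such term. Date variance excluded by default,
#' as for [repeatability()].
#'
#' @inheritParams repeatability
#' @param a_term name of the additive-genetic (animal) term.
#' @return Numeric vector of per-draw heritabilities in `[0, 1]`.
#' @export
heritability <- function(fit, category = NULL, a_term = "animal",
                         pe_term = "individual", include_date = FALSE) {
  m <- if (inherits(fit, "qgfit")) fit$samples else as.matrix(fit)
  a_nm <- if (is.null(category)) paste0(a_term, ".var") else
    paste0(a_term, ".", category, ":", category)
  if (!a_nm %in% colnames(m)) {
    stop("no additive-genetic term '", a_term, "' in the samples; ",
         "was the model fitted with a pedigree?")
  }
  a <- m[, a_nm]
  cp <- ratio_components(fit, category, pe_term, include_date)
  a / (Reduce(`+`, cp) + a)
}

#' Evolvability (mean-standardized additive genetic variance)
#'
#' Per draw, `I_A = s2_a / trait_mean^2 * 100`. The trait mean enters as a
#' single posterior-mode value so that only the uncertainty in the additive
#' variance propagates; evolvability diverges as the trait mean approaches
#' zero, so a zero mean is an error.
#'
#' @param a_draws per-draw additive genetic variances.
#' @param trait_mean_mode posterior mode of the trait mean (scalar, nonzero).
#' @return Numeric vector of per-draw evolvabilities (percent).
#' @export
evolvability <- function(a_draws, trait_mean_mode) {
  stopifnot(is.numeric(trait_mean_mode), length(trait_mean_mode) == 1L)
  if (trait_mean_mode == 0) {
    stop("trait mean mode is zero: evolvability is undefined ",
         "(it diverges as the trait mean approaches zero)")
  }
  a_draws / trait_mean_mode^2 * 100
}

#' Genetic correlation between two categories or reaction-norm components
#'
#' Per draw the correlation is `C_ij / sqrt(C_ii * C_jj)` from an
#' unstructured covariance term.
#'
#' @param fit a `qgfit` or named draws matrix.
#' @param i,j labels of the two components (e.g. `"cold"`, `"hot"`, or
#'   reaction-norm labels like `"(Intercept)"`, `"tc_inc"`).
#' @param term covariance term name.
#' @return Numeric vector of per-draw correlations in `[-1, 1]`.
#' @export
genetic_correlation <- function(fit, i, j, term = "animal") {
  stopifnot(!identical(i, j))
  m <- if (inherits(fit, "qgfit")) fit$samples else as.matrix(fit)
  cij <- paste0(term, ".", i, ":", j)
  if (!cij %in% colnames(m)) cij <- paste0(term, ".", j, ":", i)
  if (!cij %in% colnames(m)) {
    stop("covariance '", term, ".", i, ":", j, "' not present in the samples")
  }
  num <- m[, cij]
  den <- sqrt(vc_draws(m, term, i) * vc_draws(m, term, j))
  r <- num / den
  if (any(!is.finite(r)) || any(abs(r) > 1 + 1e-8)) {
    stop("non-positive-definite covariance draw encountered")
  }
  pmin(pmax(r, -1), 1)
}

#' Posterior draws of the trait mean in one category
#'
#' Fixed-effect draws of the expected head-neck deviation for the category
#' (reference-coded intercept plus the category contrast), covariates at
#' their centered zero. Used as the denominator of [evolvability()] via its
#' posterior mode.
#'
#' @param fit a `qgfit` from the category model.
#' @param category category label.
#' @param category_col name of the category factor in the fixed design.
#' @return Numeric vector of per-draw trait means.
#' @export
trait_mean_draws <- function(fit, category, category_col = "category") {
  m <- if (inherits(fit, "qgfit")) fit$samples else as.matrix(fit)
  if (!"(Intercept)" %in% colnames(m)) {
    stop("model has no intercept; cannot reconstruct the trait mean")
  }
  d <- m[, "(Intercept)"]
  contrast <- paste0(category_col, category)
  if (contrast %in% colnames(m)) d <- d + m[, contrast]
  d
}

#' Tidy quantitative-genetic summary of a category-model fit
#'
#' Draw-wise repeatability, heritability (when a pedigree-linked term is
#' present), evolvability and pairwise genetic correlations, summarized as
#' posterior mode and 95% HPD interval per category.
#'
#' @param fit a `qgfit` from the category model.
#' @param categories category labels.
#' @inheritParams heritability
#' @return data.frame `quantity, category, mode, hpd_low, hpd_high`.
#' @export
quantgen_summary <- function(fit, categories = c("cold", "benign", "hot"),
                             a_term = "animal", pe_term = "individual",
                             include_date = FALSE) {
  has_a <- any(startsWith(colnames(fit$samples), paste0(a_term, ".")))
  rows <- list()
  add <- function(quantity, category, draws) {
    hpd <- hpd_interval(draws)
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, category = category,
      mode = posterior_mode(draws), hpd_low = hpd[1L], hpd_high = hpd[2L],
      stringsAsFactors = FALSE)
  }
  for (cat in categories) {
    add("repeatability", cat,
        repeatability(fit, cat, pe_term, include_date))
    if (has_a) {
      add("heritability", cat,
          heritability(fit, cat, a_term, pe_term, include_date))
      tm <- posterior_mode(trait_mean_draws(fit, cat))
      if (tm != 0) {
        add("evolvability", cat, evolvability(vc_draws(fit, a_term, cat), tm))
      }
    }
  }
  if (has_a && length(categories) > 1L) {
    prs <- utils::combn(categories, 2L)
    for (k in seq_len(ncol(prs))) {
      add("genetic_correlation", paste(prs[, k], collapse = ":"),
          genetic_correlation(fit, prs[1L, k], prs[2L, k], a_term))
    }
  }
  do.call(rbind, rows)
}

#' Write a quantitative-genetic summary as CSV
#' @param summary data.frame from [quantgen_summary()].
#' @param path file path.
#' @export
write_quantgen_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
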