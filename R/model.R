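#' MCMC schedule settings
#'
#' Defaults mirror the long production schedule used for the Gaussian
#' analyses (5,100,000 iterations, 100,000 burn-in, thinning 4,000). The
#' threshold selection analysis uses a longer schedule
#' (`qg_settings(31500000, 1500000, 10000)`). Test-scale runs pass reduced
#' schedules explicitly.
#'
#' @param nitt total iterations.
#' @param burnin iterations discarded.
#' @param thin keep every `thin`-th iteration after burn-in.
#' @return A `qg_settings` list.
#' @export
qg_settings <- function(nitt = 5100000, burnin = 100000, thin = 4000) {
  nitt <- as.numeric(nitt); burnin <- as.numeric(burnin); thin <- as.numeric(thin)
  stopifnot(nitt >= 1, burnin >= 0, thin >= 1, burnin < nitt)
  structure(list(nitt = nitt, burnin = burnin, thin = thin),
            class = "qg_settings")
}

#' Declarative mixed-model specification
#'
#' Describes a Bayesian linear mixed model: response column, family, fixed
#' formula, random terms and residual partition. Random-term designs are
#' given as character vectors: `"1"` for an intercept column, `"cat(col)"`
#' for factor expansion over a category column (one column per level,
#' jointly an unstructured q x q covariance), or a set of covariate column
#' names (random-regression columns). A term with `pedigree = TRUE` has its
#' levels covariance-linked through the additive relationship matrix
#' (an animal-model term).
#'
#' @param response response column name.
#' @param fixed right-hand-side formula as character, e.g.
#'   `"~ category + time_scaled"`. Use `"~ 0"` for no fixed effects.
#' @param family `"gaussian"` or `"threshold"` (binary liability, probit
#'   link, residual liability variance fixed at 1).
#' @param random named list of random terms, each a list with fields
#'   `group` (grouping column), `design` (see above) and optional
#'   `pedigree` flag.
#' @param residual `"homogeneous"` or `"by:<column>"` for a separate
#'   residual variance per level of `<column>`.
#' @param settings a [qg_settings()] schedule.
#' @return A `qg_model` object.
#' @examples
#' qg_model("head_neck_dev", "~ category",
#'          random = list(individual = list(group = "individual_id",
#'                                          design = "cat(category)")),
#'          residual = "by:category")
#' @export
qg_model <- function(response, fixed = "~ 1", family = c("gaussian", "threshold"),
                     random = list(), residual = "homogeneous",
                     settings = qg_settings()) {
  family <- match.arg(family)
  stopifnot(is.character(response), length(response) == 1L,
            is.character(fixed), length(fixed) == 1L)
  if (length(random)) {
    if (is.null(names(random)) || any(!nzchar(names(random)))) {
      stop("random terms must be named")
    }
    for (nm in names(random)) {
      t <- random[[nm]]
      if (is.null(t$group) || is.null(t$design)) {
        stop("random term '", nm, "' needs fields 'group' and 'design'")
      }
      random[[nm]]$pedigree <- isTRUE(t$pedigree)
    }
  }
  stopifnot(is.character(residual), length(residual) == 1L)
  if (!identical(residual, "homogeneous") && !startsWith(residual, "by:")) {
    stop("residual must be 'homogeneous' or 'by:<column>'")
  }
  structure(list(response = response, fixed = fixed, family = family,
                 random = random, residual = residual,
                 settings = unclass(settings)),
            class = "qg_model")
}

#' @export
#' @method print qg_model
print.qg_model <- function(x, ...) {
  cat("qg_model:", x$family, "response:", x$response, "\n")
  cat("  fixed:   ", x$fixed, "\n")
  for (nm in names(x$random)) {
    t <- x$random[[nm]]
    cat("  random:  ", nm, "~", paste(t$design, collapse = " + "),
        "| group:", t$group, if (t$pedigree) "[pedigree-linked]" else "", "\n")
  }
  cat("  residual:", x$residual, "\n")
  invisible(x)
}

#' Serialize / restore a model specification as YAML
#' @param model a `qg_model`.
#' @return `model_to_yaml`: a YAML string; `model_from_yaml`: a `qg_model`.
#' @export
model_to_yaml <- function(model) {
  stopifnot(inherits(model, "qg_model"))
  yaml::as.yaml(unclass(model))
}

#' @param text YAML string produced by [model_to_yaml()].
#' @rdname model_to_yaml
#' @export
model_from_yaml <- function(text) {
  x <- yaml::yaml.load(text)
  qg_model(x$response, x$fixed, x$family,
           random = lapply(x$random, function(t) {
             list(group = t$group, design = unlist(t$design),
                  pedigree = isTRUE(t$pedigree))
           }),
           residual = x$residual,
           settings = qg_settings(x$settings$nitt, x$settings$burnin,
                                  x$settings$thin))
}

#' Build design structures for a model specification
#'
#' Expands the fixed formula to a full-rank design matrix (reference-level
#' coding; rank deficiency is an error naming the aliased columns), encodes
#' each random term as a level index plus per-observation design values,
#' and partitions observations into residual blocks.
#'
#' @param frame observation data.frame.
#' @param model a [qg_model()].
#' @param pedigree a `qg_pedigree`, required when any term has
#'   `pedigree = TRUE`. Pedigree-linked terms (and any term sharing their
#'   grouping factor) are indexed over all pedigree ids.
#' @return A list with elements `y`, `X`, `terms`, `groups`, `rblock`,
#'   `rlabels`, `par_names` (internal layout consumed by [qgfit()]).
#' @export
build_design <- function(frame, model, pedigree = NULL) {
  stopifnot(inherits(model, "qg_model"))
  if (!model$response %in% names(frame)) {
    stop("response column '", model$response, "' not found")
  }
  y <- frame[[model$response]]
  if (model$family == "threshold") {
    if (!all(y %in% c(0, 1))) stop("threshold family requires a 0/1 response")
    if (length(unique(y)) < 2L) {
      stop("degenerate binary response (complete separation): all values are ", y[1])
    }
  } else {
    if (!is.numeric(y) || anyNA(y)) stop("gaussian response must be numeric without NA")
  }
  n <- nrow(frame)

  # fixed design
  fml <- stats::as.formula(model$fixed)
  vars <- all.vars(fml)
  missing_cols <- setdiff(vars, names(frame))
  if (length(missing_cols)) {
    stop("fixed-effect column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  X <- stats::model.matrix(fml, frame)
  if (ncol(X) > 0L) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("rank-deficient fixed design; aliased column(s): ",
           paste(aliased, collapse = ", "))
    }
  }

  # pedigree level space shared by any term grouped like a pedigree term
  ped_groups <- character(0)
  if (length(model$random)) {
    ped_groups <- unique(vapply(
      Filter(function(t) t$pedigree, model$random),
      function(t) t$group, character(1)))
  }
  if (length(ped_groups) && is.null(pedigree)) {
    stop("model contains a pedigree-linked term but no pedigree was supplied")
  }

  terms <- list()
  for (nm in names(model$random)) {
    tspec <- model$random[[nm]]
    if (!tspec$group %in% names(frame)) {
      stop("random-term grouping column '", tspec$group, "' not found")
    }
    gvals <- as.character(frame[[tspec$group]])
    if (tspec$group %in% ped_groups) {
      levs <- pedigree$id
      miss <- setdiff(unique(gvals), levs)
      if (length(miss)) {
        stop("individuals missing from the pedigree: ",
             paste(utils::head(miss, 5L), collapse = ", "))
      }
    } else {
      levs <- sort(unique(gvals))
    }
    level <- match(gvals, levs) - 1L

    d <- tspec$design
    if (length(d) == 1L && identical(d, "1")) {
      Z <- matrix(1, n, 1L)
      labels <- "var"
    } else if (length(d) == 1L && grepl("^cat\\(", d)) {
      col <- sub("^cat\\((.*)\\)$", "\\1", d)
      if (!col %in% names(frame)) stop("category column '", col, "' not found")
      f <- as.factor(frame[[col]])
      labels <- levels(f)
      Z <- matrix(0, n, length(labels))
      Z[cbind(seq_len(n), as.integer(f))] <- 1
    } else {
      labels <- d
      Z <- matrix(0, n, length(d))
      for (j in seq_along(d)) {
        if (identical(d[j], "1")) {
          Z[, j] <- 1
          labels[j] <- "(Intercept)"
        } else {
          if (!d[j] %in% names(frame)) {
            stop("random-design column '", d[j], "' not found")
          }
          Z[, j] <- frame[[d[j]]]
        }
      }
    }
    terms[[nm]] <- list(name = nm, level = level, Z = Z, nlev = length(levs),
                        levels = levs, labels = labels, q = ncol(Z),
                        pedigree = tspec$pedigree, group = tspec$group)
  }

  # update groups: terms sharing a grouping factor are sampled jointly
  groups <- list()
  if (length(terms)) {
    byg <- split(seq_along(terms),
                 vapply(terms, function(t) t$group, character(1)))
    groups <- unname(byg[order(vapply(byg, min, 1L))])
  }

  # residual partition
  if (identical(model$residual, "homogeneous")) {
    rblock <- rep(0L, n)
    rlabels <- "units"
  } else {
    col <- sub("^by:", "", model$residual)
    if (!col %in% names(frame)) stop("residual category column '", col, "' not found")
    f <- as.factor(frame[[col]])
    rblock <- as.integer(f) - 1L
    rlabels <- levels(f)
  }

  par_names <- colnames(X)
  for (t in terms) {
    if (t$q == 1L) {
      par_names <- c(par_names, paste0(t$name, ".", t$labels))
    } else {
      for (j in seq_len(t$q)) {
        for (i in j:t$q) {
          par_names <- c(par_names,
                         paste0(t$name, ".", t$labels[i], ":", t$labels[j]))
        }
      }
    }
  }
  par_names <- c(par_names, paste0("R.", rlabels))

  list(y = y, X = X, terms = terms, groups = groups,
       rblock = rblock, rlabels = rlabels, par_names = par_names, n = n)
}

default_prior <- function(q) {
  # univariate: inverse-gamma scale 0.001, shape 0.001  <=>  V = 1, nu = 0.002
  # generalized to V = diag(q), nu = q - 1 + 0.002 for q x q terms
  list(V = diag(q), nu = q - 1 + 0.002)
}

#' Fit a Bayesian linear mixed model by Gibbs sampling
#'
#' The engine behind all analyses in the package: Gaussian or threshold
#' (binary-liability) response, any number of random terms with unstructured
#' covariances, optional pedigree linkage through the sparse inverse of the
#' additive relationship matrix, and homogeneous or per-category residual
#' variances. All full conditionals are conjugate (multivariate normal for
#' location effects, inverse-Wishart for covariances, inverse-gamma for
#' residual variances, truncated normal for liabilities). Identical
#' `(model, data, prior, seed)` give bit-identical retained draws.
#'
#' @param model a [qg_model()] or a recipe object (`qg_recipe`) carrying its
#'   own prepared data.
#' @param data observation data.frame (ignored when `model` is a recipe).
#' @param pedigree a `qg_pedigree` for pedigree-linked terms.
#' @param settings a [qg_settings()] schedule overriding the model's.
#' @param prior optional named list of per-term priors
#'   (`list(V = <q x q>, nu = <scalar>)`), plus optional
#'   `residual = list(shape =, rate =)`.
#' @param seed integer seed (mandatory source of all randomness).
#' @return A `qgfit` object: retained draws (`$samples`, columns named),
#'   posterior-mean fitted values, posterior-mean random effects, and the
#'   model metadata. See [summary.qgfit()].
#' @examples
#' set.seed(1)
#' d <- data.frame(y = rnorm(60), g = rep(letters[1:12], each = 5))
#' m <- qg_model("y", "~ 1",
#'               random = list(g = list(group = "g", design = "1")))
#' fit <- qgfit(m, d, settings = qg_settings(600, 100, 2), seed = 42)
#' summary(fit)
#' @export
qgfit <- function(model, data = NULL, pedigree = NULL, settings = NULL,
                  prior = NULL, seed = 1L) {
  if (inherits(model, "qg_recipe")) {
    if (is.null(data)) data <- model$data
    if (is.null(pedigree)) pedigree <- model$pedigree
    model <- model$model
  }
  stopifnot(inherits(model, "qg_model"), is.data.frame(data))
  if (is.null(settings)) settings <- model$settings
  settings <- qg_settings(settings$nitt, settings$burnin, settings$thin)

  des <- build_design(data, model, pedigree)
  family <- match(model$family, c("gaussian", "threshold")) - 1L

  cterms <- list()
  for (t in des$terms) {
    pr <- if (!is.null(prior[[t$name]])) prior[[t$name]] else default_prior(t$q)
    V <- as.matrix(pr$V)
    if (!isSymmetric(unname(V), tol = 1e-8) ||
        inherits(try(chol(V), silent = TRUE), "try-error")) {
      stop("prior V for term '", t$name, "' is not symmetric positive definite")
    }
    if (!is.numeric(pr$nu) || pr$nu <= 0) {
      stop("prior nu for term '", t$name, "' must be > 0")
    }
    ct <- list(level = t$level, Z = t$Z, nlev = t$nlev, V = V, nu = pr$nu,
               Ap = NULL, Ai = NULL, Ax = NULL)
    if (t$pedigree) {
      Ainv <- ainverse(pedigree)
      ct$Ap <- Ainv@p
      ct$Ai <- Ainv@i
      ct$Ax <- Ainv@x
    }
    cterms[[t$name]] <- ct
  }
  rprior <- if (!is.null(prior$residual)) prior$residual else
    list(shape = 0.001, rate = 0.001)

  y <- des$y
  if (family == 1L) {
    y01 <- as.integer(des$y)
    y <- ifelse(y01 == 1L, 0.5, -0.5)  # liability start values
  } else {
    y01 <- integer(des$n)
  }

  set.seed(as.integer(seed))
  res <- .gibbs_cpp(as.numeric(y), des$X, unname(cterms), des$groups,
                    des$rblock, length(des$rlabels),
                    rprior$shape, rprior$rate, family, y01,
                    as.integer(settings$nitt), as.integer(settings$burnin),
                    as.integer(settings$thin))

  samples <- res$samples
  colnames(samples) <- des$par_names
  u_mean <- res$u_mean
  names(u_mean) <- names(cterms)
  for (nm in names(u_mean)) {
    rownames(u_mean[[nm]]) <- des$terms[[nm]]$levels
    colnames(u_mean[[nm]]) <- des$terms[[nm]]$labels
  }

  structure(list(samples = samples, model = model, settings = settings,
                 seed = as.integer(seed), family = model$family,
                 n = des$n, p = ncol(des$X), fixed_names = colnames(des$X),
                 terms = lapply(des$terms, function(t) {
                   t[c("name", "labels", "q", "nlev", "pedigree")]
                 }),
                 rlabels = des$rlabels,
                 response = des$y, fitted = as.numeric(res$fitted),
                 u_mean = u_mean, nsave = res$nsave),
            class = "qgfit")
}
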