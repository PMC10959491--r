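#' Build and validate a pedigree
#'
#' Constructs a validated, topologically sorted pedigree from parent
#' pointers. Every parent precedes its offspring in the returned object,
#' which is the ordering required by the tabular method ([amatrix()]) and
#' by Henderson's rules for the sparse inverse ([ainverse()]).
#'
#' Unknown parents (`NA` or empty string) are treated as unrelated,
#' non-inbred founders. With `strict_parents = TRUE` (default) a parent id
#' that never appears as an individual is an error; with `FALSE` such
#' parents are inserted as founders.
#'
#' @param id character vector of individual identifiers (unique, nonempty).
#' @param sire,dam parent identifiers; `NA` or `""` when unknown.
#' @param subspecies optional founder population label (e.g. `"SAB"`,
#'   `"ZB"`, `"KR"`); must be `NA` for non-founders.
#' @param cohort optional integer birth-year/generation label.
#' @param strict_parents error on parent ids absent from `id`? If `FALSE`
#'   missing parents are auto-inserted as founders.
#' @return A `qg_pedigree`: a data.frame with columns `id`, `sire`, `dam`,
#'   `subspecies`, `cohort`, sorted parents-before-offspring.
#' @examples
#' ped <- pedigree(id = c("O1", "P1", "P2"),
#'                 sire = c("P1", NA, NA),
#'                 dam  = c("P2", NA, NA))
#' ped$id  # parents first
#' @export
pedigree <- function(id, sire = NA, dam = NA, subspecies = NULL,
                     cohort = NULL, strict_parents = TRUE) {
  id <- as.character(id)
  n <- length(id)
  norm_parent <- function(x) {
    x <- as.character(rep_len(x, n))
    x[!is.na(x) & !nzchar(x)] <- NA_character_
    x
  }
  sire <- norm_parent(sire)
  dam <- norm_parent(dam)
  if (n == 0L) stop("pedigree is empty")
  if (anyNA(id) || any(!nzchar(id))) stop("individual ids must be nonempty")
  if (anyDuplicated(id)) {
    stop("duplicate individual id: ", id[duplicated(id)][1L])
  }
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id)) {
    stop("an individual cannot be its own parent")
  }

  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    if (strict_parents) {
      stop("parent id(s) not present as individuals: ",
           paste(utils::head(parents, 5L), collapse = ", "),
           " (use strict_parents = FALSE to insert them as founders)")
    }
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
    if (!is.null(subspecies)) {
      subspecies <- c(rep(NA_character_, length(parents)),
                      as.character(rep_len(subspecies, n)))
    }
    if (!is.null(cohort)) {
      cohort <- c(rep(NA_integer_, length(parents)),
                  as.integer(rep_len(cohort, n)))
    }
    n <- length(id)
  }
  subspecies <- if (is.null(subspecies)) rep(NA_character_, n) else
    as.character(rep_len(subspecies, n))
  subspecies[!is.na(subspecies) & !nzchar(subspecies)] <- NA_character_
  cohort <- if (is.null(cohort)) rep(NA_integer_, n) else
    as.integer(rep_len(cohort, n))

  is_founder <- is.na(sire) & is.na(dam)
  bad_label <- !is.na(subspecies) & !is_founder
  if (any(bad_label)) {
    stop("founder_subspecies label on non-founder: ", id[bad_label][1L])
  }

  # Kahn topological sort, parents before offspring
  idx <- match(id, id)
  si <- match(sire, id)
  di <- match(dam, id)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    on_cycle <- setdiff(seq_len(n), order)
    stop("pedigree contains a cycle involving individual: ", id[on_cycle[1L]])
  }

  out <- data.frame(id = id[order], sire = sire[order], dam = dam[order],
                    subspecies = subspecies[order], cohort = cohort[order],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("qg_pedigree", "data.frame")
  out
}

#' Read a pedigree from CSV
#'
#' Expects header `id,sire,dam,subspecies,cohort` (the last two optional);
#' empty strings denote unknown parents.
#'
#' @param path file path.
#' @inheritParams pedigree
#' @return A `qg_pedigree`.
#' @export
read_pedigree_csv <- function(path, strict_parents = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "sire", "dam")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("pedigree CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  pedigree(df$id, df$sire, df$dam,
           subspecies = if ("subspecies" %in% names(df)) df$subspecies,
           cohort = if ("cohort" %in% names(df)) suppressWarnings(as.integer(df$cohort)),
           strict_parents = strict_parents)
}

#' Write a pedigree to CSV
#' @param ped a `qg_pedigree`.
#' @param path file path.
#' @export
write_pedigree_csv <- function(ped, path) {
  stopifnot(inherits(ped, "qg_pedigree"))
  df <- as.data.frame(ped)
  df$sire[is.na(df$sire)] <- ""
  df$dam[is.na(df$dam)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
#' @method print qg_pedigree
print.qg_pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat("Pedigree:", nrow(x), "individuals,", nf, "founders\n")
  if (!all(is.na(x$subspecies))) {
    tab <- table(x$subspecies, useNA = "no")
    cat("Founder subspecies:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Additive (numerator) relationship matrix
#'
#' Computes `A` by the tabular method: founders have `A_ii = 1`; an
#' individual with parents `s`, `d` has `A_ii = 1 + A_sd / 2` and
#' `A_ij = (A_js + A_jd) / 2` for earlier individuals `j`, with unknown
#' parents contributing zero. `A` is twice the kinship matrix; diagonals
#' are `1 + F` with `F` the inbreeding coefficient.
#'
#' @param ped a `qg_pedigree` (sorted; as returned by [pedigree()]).
#' @return Dense symmetric matrix with ids as dimnames.
#' @examples
#' ped <- pedigree(c("P1", "P2", "O"), c(NA, NA, "P1"), c(NA, NA, "P2"))
#' amatrix(ped)["O", "P1"]  # 0.5
#' @export
amatrix <- function(ped) {
  stopifnot(inherits(ped, "qg_pedigree"))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  A <- .amatrix_cpp(si - 1L, di - 1L)
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding (Mendelian sampling variances computed
#' from parental inbreeding coefficients taken off the tabular-method
#' diagonal). Exact for any pedigree, and sparse: nonzeros only among
#' parents, offspring and mates.
#'
#' @inheritParams amatrix
#' @return A [Matrix::dgCMatrix-class] with ids as dimnames.
#' @export
ainverse <- function(ped) {
  stopifnot(inherits(ped, "qg_pedigree"))
  n <- nrow(ped)
  Fi <- inbreeding(amatrix(ped))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  ii <- jj <- integer(9L * n)
  xx <- numeric(9L * n)
  m <- 0L
  push <- function(i, j, v) {
    m <<- m + 1L
    ii[m] <<- i; jj[m] <<- j; xx[m] <<- v
  }
  for (k in seq_len(n)) {
    s <- si[k]; d <- di[k]
    np <- sum(!is.na(c(s, d)))
    msv <- if (np == 2L) 0.5 - 0.25 * (Fi[s] + Fi[d])
    else if (np == 1L) 0.75 - 0.25 * Fi[c(s, d)[!is.na(c(s, d))]]
    else 1
    a <- 1 / msv
    push(k, k, a)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        push(k, p, -0.5 * a); push(p, k, -0.5 * a)
        push(p, p, 0.25 * a)
      }
    }
    if (!is.na(s) && !is.na(d)) {
      push(s, d, 0.25 * a); push(d, s, 0.25 * a)
    }
  }
  ii <- ii[seq_len(m)]; jj <- jj[seq_len(m)]; xx <- xx[seq_len(m)]
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  methods::as(Ainv, "CsparseMatrix")
}

#' Inbreeding coefficients from a relationship matrix
#'
#' `F_i = A_ii - 1`. Errors when a diagonal entry lies outside `[1, 2)`,
#' which would violate the relationship-matrix invariants.
#'
#' @param A additive relationship matrix (ids as dimnames).
#' @return Named numeric vector of inbreeding coefficients in `[0, 1)`.
#' @export
inbreeding <- function(A) {
  d <- diag(A)
  if (any(d < 1 - 1e-12) || any(d >= 2)) {
    stop("relationship-matrix diagonal outside [1, 2): invalid matrix")
  }
  f <- pmax(d - 1, 0)
  names(f) <- rownames(A)
  f
}

#' Expected subspecies fractions and hybrid classification
#'
#' Each founder contributes 1 to its own label; every other individual's
#' fraction is the average of its parents' fractions. An individual is
#' classified as its majority label when that fraction is at least
#' `threshold` (default 0.85), otherwise as `"hybrid"`.
#'
#' @inheritParams amatrix
#' @param threshold minimum expected relatedness for a pure-class call.
#' @return List with `fractions` (individuals x labels matrix) and `class`
#'   (named character vector).
#' @export
subspecies_fractions <- function(ped, threshold = 0.85) {
  stopifnot(inherits(ped, "qg_pedigree"))
  founder <- is.na(ped$sire) & is.na(ped$dam)
  if (any(founder & is.na(ped$subspecies))) {
    stop("founder without subspecies label: ",
         ped$id[founder & is.na(ped$subspecies)][1L])
  }
  labels <- sort(unique(stats::na.omit(ped$subspecies)))
  n <- nrow(ped)
  fr <- matrix(0, n, length(labels), dimnames = list(ped$id, labels))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (k in seq_len(n)) {
    if (founder[k]) {
      fr[k, ped$subspecies[k]] <- 1
    } else {
      fs <- if (is.na(si[k])) NULL else fr[si[k], ]
      fd <- if (is.na(di[k])) NULL else fr[di[k], ]
      if (is.null(fs) || is.null(fd)) {
        stop("individual ", ped$id[k], " has an unknown parent; subspecies ",
             "fractions require labelled founders for all lineages")
      }
      fr[k, ] <- (fs + fd) / 2
    }
  }
  cls <- apply(fr, 1L, function(z) {
    j <- which.max(z)
    if (z[j] >= threshold) colnames(fr)[j] else "hybrid"
  })
  list(fractions = fr, class = cls)
}

#' Write a relationship matrix as CSV (id header row and column)
#' @param A relationship matrix.
#' @param path file path.
#' @export
write_amatrix_csv <- function(A, path) {
  utils::write.csv(as.data.frame(A), path, row.names = TRUE)
  invisible(path)
}
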