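# Independent oracles and small fixture builders used across the suite.

# Recursive kinship coefficient phi(i, j) on a sorted pedigree, memoized.
# phi(i, i) = 0.5 * (1 + phi(s_i, d_i)); phi(i, j) for i later than j is
# 0.5 * (phi(s_i, j) + phi(d_i, j)); unknown parents contribute 0.
# The additive relationship is 2 * phi.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  phi <- matrix(NA_real_, n, n)
  get_phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    if (!is.na(phi[i, j])) return(phi[i, j])
    v <- if (i == j) {
      ps <- if (is.na(si[i])) 0L else si[i]
      pd <- if (is.na(di[i])) 0L else di[i]
      0.5 * (1 + get_phi(ps, pd))
    } else {
      ps <- if (is.na(si[i])) 0L else si[i]
      pd <- if (is.na(di[i])) 0L else di[i]
      0.5 * (get_phi(ps, j) + get_phi(pd, j))
    }
    phi[i, j] <<- v
    phi[j, i] <<- v
    v
  }
  out <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    out[i, j] <- out[j, i] <- get_phi(i, j)
  }
  out
}

# Random valid pedigree with up to nmax individuals: founders plus
# descendants whose parents are drawn from earlier individuals.
random_pedigree <- function(nmax = 60) {
  nf <- sample(3:8, 1)
  n <- sample((nf + 2):nmax, 1)
  id <- paste0("I", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    pool <- id[seq_len(i - 1L)]
    pair <- sample(pool, 2)
    if (stats::runif(1) < 0.1) pair[2] <- NA  # occasional unknown dam
    sire[i] <- pair[1]
    dam[i] <- pair[2]
  }
  pedigree(id, sire, dam)
}

# Independent natural cubic spline (tridiagonal solve for second
# derivatives with natural boundary conditions), evaluated at xq.
natural_spline_oracle <- function(x, y, xq) {
  n <- length(x)
  h <- diff(x)
  a <- c(0, h[-(n - 1)])
  b <- c(1, 2 * (h[-(n - 1)] + h[-1]), 1)
  cc <- c(h[-1], 0)
  d <- c(0, 6 * diff(diff(y) / h), 0)
  # Thomas algorithm
  for (i in 2:n) {
    w <- a[i - 1] / b[i - 1]
    b[i] <- b[i] - w * cc[i - 1]
    d[i] <- d[i] - w * d[i - 1]
  }
  m <- numeric(n)
  m[n] <- d[n] / b[n]
  for (i in (n - 1):1) m[i] <- (d[i] - cc[i] * m[i + 1]) / b[i]
  vapply(xq, function(q) {
    k <- findInterval(q, x, all.inside = TRUE)
    t1 <- x[k + 1] - q
    t2 <- q - x[k]
    (m[k] * t1^3 + m[k + 1] * t2^3) / (6 * h[k]) +
      (y[k] / h[k] - m[k] * h[k] / 6) * t1 +
      (y[k + 1] / h[k] - m[k + 1] * h[k] / 6) * t2
  }, 0)
}

# Tiny observation frame with all derived columns, for design/recipe tests.
tiny_observations <- function(n = 60, seed = 1) {
  set.seed(seed)
  air_t <- stats::runif(n, 0, 40)
  tc <- temperature_change_transform(air_t, 20, max(abs(air_t - 20)))
  hrs <- stats::runif(n, 6, 17)
  data.frame(
    image_id = sprintf("I%03d", seq_len(n)),
    individual_id = sample(paste0("F", 1:12), n, replace = TRUE),
    date = sample(c("2014-10-01", "2014-10-12", "2014-11-03"), n, TRUE),
    year = 2014L,
    enclosure_id = sample(c("E1", "E2", "E3"), n, TRUE),
    air_t = air_t,
    head_t = 30 + stats::rnorm(n),
    neck_t = 31 + stats::rnorm(n),
    head_neck_dev = stats::rnorm(n),
    temp_change = tc$temp_change,
    direction = tc$direction,
    tc_dec = tc$temp_change * (tc$direction == "decrease"),
    tc_inc = tc$temp_change * (tc$direction == "increase"),
    category = assign_temperature_category(air_t),
    subspecies_class = sample(c("SAB", "ZB"), n, TRUE),
    within_category_dev = standardize_covariate(air_t, assign_temperature_category(air_t)),
    time_scaled = standardize_covariate(hrs),
    time_scaled_sq = standardize_covariate(hrs)^2,
    stringsAsFactors = FALSE)
}
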