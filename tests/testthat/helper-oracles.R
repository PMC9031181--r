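# Independent oracles, written as literal transcriptions so they stay
# independent of the vectorized production code.

# double-loop 2SFCA on planar coordinates
oracle_two_step_fca <- function(com, grn, d0) {
  n <- nrow(com)
  m <- nrow(grn)
  G <- function(d) {
    if (d > d0) 0 else (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5))
  }
  dist_ij <- function(i, j) {
    sqrt((com$lon[i] - grn$lon[j])^2 + (com$lat[i] - grn$lat[j])^2)
  }
  R <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    den <- 0
    for (k in seq_len(n)) {
      d <- dist_ij(k, j)
      if (d <= d0) den <- den + G(d) * com$households[k]
    }
    if (den > 0) R[j] <- grn$area_m2[j] / den
  }
  A <- numeric(n)
  for (i in seq_len(n)) {
    for (l in seq_len(m)) {
      d <- dist_ij(i, l)
      if (d <= d0 && !is.na(R[l])) A[i] <- A[i] + G(d) * R[l]
    }
  }
  list(A = A, R = R)
}

# pairwise weighted mean-absolute-difference Gini
oracle_gini_pairwise <- function(w, x) {
  W <- sum(w)
  mu <- sum(w * x) / W
  tot <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(x)) {
      tot <- tot + w[i] * w[j] * abs(x[i] - x[j])
    }
  }
  tot / (2 * W^2 * mu)
}

# trapezoid area under the grouped Lorenz curve
oracle_gini_lorenz <- function(w, x) {
  o <- order(x)
  w <- w[o]
  x <- x[o]
  cp <- c(0, cumsum(w) / sum(w))
  cl <- c(0, cumsum(w * x) / sum(w * x))
  1 - sum(diff(cp) * (utils::head(cl, -1) + utils::tail(cl, -1)))
}

# random planar city instance
random_instance <- function(n_com, n_grn, extent = 10000) {
  list(
    com = tibble::tibble(
      id = sprintf("c%03d", seq_len(n_com)),
      lon = stats::runif(n_com, 0, extent),
      lat = stats::runif(n_com, 0, extent),
      households = sample(1:2000, n_com, replace = TRUE)
    ),
    grn = tibble::tibble(
      id = sprintf("g%03d", seq_len(n_grn)),
      lon = stats::runif(n_grn, 0, extent),
      lat = stats::runif(n_grn, 0, extent),
      area_m2 = stats::runif(n_grn, 1e4, 5e5)
    )
  )
}
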