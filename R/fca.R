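#' Truncated Gaussian distance-decay kernel
#'
#' The decay weight used throughout the 2SFCA computation:
#' \deqn{G(d, d_0) = \frac{e^{-\frac{1}{2}(d/d_0)^2} - e^{-\frac{1}{2}}}
#'                        {1 - e^{-\frac{1}{2}}} \quad (d \le d_0),}
#' and 0 beyond the catchment radius. The kernel is 1 at distance 0, falls
#' continuously to exactly 0 at \eqn{d = d_0}, and is 0 outside. Vectorized
#' over `d`.
#'
#' @param d Distance(s) in meters, >= 0.
#' @param d0 Catchment radius in meters, > 0.
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' gaussian_decay(c(0, 500, 1000, 1500), 1000)
#' @export
gaussian_decay <- function(d, d0) {
  if (!is.numeric(d0) || length(d0) != 1L || !is.finite(d0) || d0 <= 0) {
    stop("d0 must be a single positive finite number")
  }
  if (any(d < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  g <- (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5))
  g[d > d0] <- 0
  # clamp tiny negative residue exactly at the boundary
  pmax(g, 0)
}

#' Supply-to-demand ratio per green space (2SFCA step one)
#'
#' For each supply point j, the ratio of its capacity to the decay-weighted
#' households inside its catchment:
#' \deqn{R_j = S_j / \sum_{k:\,d_{kj} \le d_0} G(d_{kj}, d_0)\,H_k.}
#' A supply point whose catchment holds no positively weighted demand
#' (empty, or boundary-only where the kernel is 0) has an undefined ratio;
#' it is returned as `NA` with `used = FALSE` and contributes to no
#' accessibility score.
#'
#' @param dmatrix Distance matrix, demand rows x supply columns (meters).
#' @param supply_m2 Numeric vector of supply capacities S_j (m² of green
#'   area), one per column of `dmatrix`.
#' @param households Numeric vector of household counts H_i, one per row.
#' @param d0 Catchment radius in meters.
#' @return A list with `R` (numeric, `NA` where unused) and `used` (logical).
#' @export
supply_demand_ratio <- function(dmatrix, supply_m2, households, d0) {
  stopifnot(length(supply_m2) == ncol(dmatrix),
            length(households) == nrow(dmatrix))
  if (any(supply_m2 <= 0)) stop("supply capacities must be positive")
  if (any(households < 1)) stop("household counts must be >= 1")
  w <- gaussian_decay(dmatrix, d0)
  denom <- as.vector(crossprod(w, households))  # sum_i G(d_ij) H_i per column j
  used <- denom > 0
  R <- ifelse(used, supply_m2 / denom, NA_real_)
  list(R = R, used = used)
}

#' Accessibility per community (2SFCA step two)
#'
#' Decay-weighted sum of reachable supply-to-demand ratios:
#' \deqn{A_i = \sum_{l:\,d_{il} \le d_0} G(d_{il}, d_0)\,R_l.}
#' Unused ratios (`NA`) contribute nothing. A community with no supply point
#' inside its catchment gets exactly 0.
#'
#' @param dmatrix Distance matrix, demand rows x supply columns (meters).
#' @param ratio Result of [supply_demand_ratio()] (or a bare numeric vector
#'   of ratios with `NA` marking unused supply points).
#' @param d0 Catchment radius in meters, same value used for `ratio`.
#' @return Numeric vector of accessibility scores A_i (m² per household).
#' @export
accessibility <- function(dmatrix, ratio, d0) {
  R <- if (is.list(ratio)) ratio$R else ratio
  stopifnot(length(R) == ncol(dmatrix))
  w <- gaussian_decay(dmatrix, d0)
  R0 <- ifelse(is.na(R), 0, R)
  as.vector(w %*% R0)
}

#' Two-step floating catchment area accessibility
#'
#' Runs both 2SFCA steps for one city at one catchment radius: each green
#' space's supply-to-demand ratio over its catchment, then each community's
#' decay-weighted sum of reachable ratios. Deterministic for a fixed input
#' ordering and invariant under row permutation (scores follow ids).
#'
#' @param communities Data frame with columns `id`, `lon`, `lat`,
#'   `households` (and optionally `city_id`, `price`).
#' @param greenspaces Data frame with columns `id`, `lon`, `lat`, `area_m2`.
#'   May have zero rows, in which case all scores are 0 (with a warning).
#' @param d0 Catchment radius in meters.
#' @param metric Distance metric, see [pairwise_distances()].
#' @param dmatrix Optional precomputed distance matrix (demand rows x supply
#'   columns) to avoid recomputation across radii.
#' @return An object of class `ugs_field`: a list with `d0`, `metric`,
#'   `community_id`, `households`, `A` (per-community accessibility, m² per
#'   household), `supply_id`, `R`, `used` (per-green-space ratio and whether
#'   any demand reaches it).
#' @examples
#' com <- data.frame(id = c("a", "b"), lon = c(0, 0), lat = c(0, 0),
#'                   households = c(100, 100))
#' grn <- data.frame(id = "g1", lon = 0, lat = 0, area_m2 = 10000)
#' two_step_fca(com, grn, d0 = 1000, metric = "euclidean")$A  # 50, 50
#' @export
two_step_fca <- function(communities, greenspaces, d0,
                         metric = c("haversine", "euclidean"),
                         dmatrix = NULL) {
  metric <- match.arg(metric)
  if (nrow(communities) == 0L) stop("no demand points: at least one community is required")
  if (nrow(greenspaces) == 0L) {
    warning("no supply points: all accessibility scores are 0")
    return(new_ugs_field(d0, metric,
                         communities$id, communities$households,
                         A = rep(0, nrow(communities)),
                         supply_id = character(0),
                         R = numeric(0), used = logical(0)))
  }
  if (is.null(dmatrix)) {
    dmatrix <- pairwise_distances(communities, greenspaces, metric)
  }
  ratio <- supply_demand_ratio(dmatrix, greenspaces$area_m2,
                               communities$households, d0)
  A <- accessibility(dmatrix, ratio, d0)
  new_ugs_field(d0, metric, communities$id, communities$households, A,
                greenspaces$id, ratio$R, ratio$used)
}

new_ugs_field <- function(d0, metric, community_id, households, A,
                          supply_id, R, used) {
  structure(
    list(d0 = d0, metric = metric,
         community_id = as.character(community_id),
         households = households, A = A,
         supply_id = as.character(supply_id), R = R, used = used),
    class = "ugs_field"
  )
}

#' @export
print.ugs_field <- function(x, ...) {
  cat(sprintf(
    "<ugs_field> d0 = %g m (%s): %d communities, %d green spaces (%d serving)\n",
    x$d0, x$metric, length(x$A), length(x$R), sum(x$used)))
  cat(sprintf("  accessibility A_i (m2/household): mean %.4g, range [%.4g, %.4g], %d zero\n",
              mean(x$A), min(x$A), max(x$A), sum(x$A == 0)))
  invisible(x)
}

#' Tidy a 2SFCA field into a per-community tibble
#'
#' @param field A `ugs_field` from [two_step_fca()].
#' @return A tibble with columns `community_id`, `households`, `radius_m`, `A`.
#' @export
field_tibble <- function(field) {
  stopifnot(inherits(field, "ugs_field"))
  tibble::tibble(
    community_id = field$community_id,
    households = field$households,
    radius_m = field$d0,
    A = field$A
  )
}
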