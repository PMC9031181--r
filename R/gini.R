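#' Lorenz curve of accessibility across communities
#'
#' Orders communities (groups) by per-household accessibility ascending and
#' accumulates household share against accessibility share, where a group's
#' accessibility share is its households times its per-household score over
#' the city total. The curve runs from (0,0) to (1,1) and is convex.
#'
#' @param households Positive group weights (household counts).
#' @param access Per-household accessibility of each group, >= 0.
#' @return A tibble with columns `p` (cumulative household share) and `L`
#'   (cumulative accessibility share), starting at (0,0).
#' @export
lorenz <- function(households, access) {
  check_gini_input(households, access)
  o <- order(access)  # ascending by per-household accessibility
  h <- households[o]
  x <- access[o]
  tibble::tibble(
    p = c(0, cumsum(h) / sum(h)),
    L = c(0, cumsum(h * x) / sum(h * x))
  )
}

check_gini_input <- function(households, access) {
  if (length(households) != length(access) || length(access) == 0L) {
    stop("households and access must be nonempty vectors of equal length")
  }
  if (any(households <= 0)) stop("household weights must be positive")
  if (any(access < 0)) stop("accessibility values must be nonnegative")
  if (sum(households * access) == 0) {
    stop("degenerate city: total accessibility is zero (see exclude_city)")
  }
  invisible(TRUE)
}

#' Grouped Gini coefficient of accessibility
#'
#' Household-weighted Gini of per-household accessibility across a city's
#' communities, each community one group. Computed as
#' \deqn{GC = \sum_i p_i y_i - 2 \sum_i \Big(\sum_{k \le i} p_k\Big) y_i + 1}
#' with groups ordered by per-household accessibility *descending*, where
#' \eqn{p_i} is group i's household share and \eqn{y_i} its share of the
#' city's total accessibility (households times per-household score). Under
#' this ordering the formula agrees exactly with the weighted
#' mean-absolute-difference Gini and with one minus twice the Lorenz-curve
#' area.
#'
#' @inheritParams lorenz
#' @return Gini coefficient in `[0, 1)`.
#' @examples
#' gini_grouped(c(100, 100), c(10, 0))  # one of two equal groups has it all: 0.5
#' @export
gini_grouped <- function(households, access) {
  check_gini_input(households, access)
  o <- order(access, decreasing = TRUE)
  h <- households[o]
  x <- access[o]
  p <- h / sum(h)
  y <- h * x / sum(h * x)
  sum(p * y) - 2 * sum(cumsum(p) * y) + 1
}

#' Classify a Gini coefficient into an inequality level
#'
#' Standard banding of accessibility inequality: `Good` below 0.3, `Normal`
#' in \[0.3, 0.4), `Warning` in \[0.4, 0.6\], `Dangerous` above 0.6.
#' Boundary ties: 0.3 and 0.4 fall in the upper band (the printed bands are
#' "<0.3" and "0.3–0.4"), 0.6 stays in `Warning` (the dangerous band is
#' strictly ">0.6").
#'
#' @param gini Numeric vector of Gini values in `[0, 1)`.
#' @return Factor with levels `Good`, `Normal`, `Warning`, `Dangerous`.
#' @examples
#' classify_inequality(c(0.1, 0.35, 0.6, 0.65))
#' @export
classify_inequality <- function(gini) {
  if (any(!is.finite(gini) | gini < 0 | gini >= 1)) {
    stop("gini values must lie in [0, 1)")
  }
  lv <- c("Good", "Normal", "Warning", "Dangerous")
  out <- ifelse(gini < 0.3, "Good",
         ifelse(gini < 0.4, "Normal",
         ifelse(gini <= 0.6, "Warning", "Dangerous")))
  factor(out, levels = lv)
}

#' City inclusion rule for equity reporting
#'
#' A city is excluded from Gini reporting when its accessibility is
#' degenerate: total accessibility zero (cities whose few sampled
#' communities reach no green space), fewer communities than
#' `min_communities` (inequality across one group is vacuous), or a share of
#' communities with nonzero accessibility below `min_nonzero_share`.
#'
#' @param field A `ugs_field` from [two_step_fca()], or a numeric vector of
#'   per-community accessibility scores.
#' @param min_communities Minimum number of communities (default 2).
#' @param min_nonzero_share Minimum share of communities with A > 0 required
#'   to report a Gini (default 0, i.e. only an all-zero city is excluded on
#'   this ground).
#' @return A list with `keep` (logical) and `reason` (`NA` when kept;
#'   otherwise `"zero accessibility"`, `"insufficient groups"` or
#'   `"nonzero share below threshold"`).
#' @export
exclude_city <- function(field, min_communities = 2, min_nonzero_share = 0) {
  A <- if (inherits(field, "ugs_field")) field$A else field
  if (length(A) < min_communities) {
    return(list(keep = FALSE, reason = "insufficient groups"))
  }
  if (all(A == 0)) {
    return(list(keep = FALSE, reason = "zero accessibility"))
  }
  if (mean(A > 0) < min_nonzero_share) {
    return(list(keep = FALSE, reason = "nonzero share below threshold"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Per-city equity summary at one radius
#'
#' Applies the inclusion rule, then the grouped Gini and its classification.
#'
#' @param field A `ugs_field` for one city at one radius.
#' @param city_id City identifier carried into the result.
#' @inheritParams exclude_city
#' @return A one-row tibble: `city_id`, `radius_m`, `n_communities`,
#'   `excluded`, `reason`, `gini`, `level`.
#' @export
gini_city <- function(field, city_id = NA_character_,
                      min_communities = 2, min_nonzero_share = 0) {
  stopifnot(inherits(field, "ugs_field"))
  verdict <- exclude_city(field, min_communities, min_nonzero_share)
  if (!verdict$keep) {
    return(tibble::tibble(
      city_id = city_id, radius_m = field$d0,
      n_communities = length(field$A),
      excluded = TRUE, reason = verdict$reason,
      gini = NA_real_, level = NA_character_
    ))
  }
  g <- gini_grouped(field$households, field$A)
  tibble::tibble(
    city_id = city_id, radius_m = field$d0,
    n_communities = length(field$A),
    excluded = FALSE, reason = NA_character_,
    gini = g, level = as.character(classify_inequality(g))
  )
}
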