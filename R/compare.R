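#' Demand-blind "traditional" accessibility baseline
#'
#' The comparison baseline that considers supply but not demand competition.
#' Default variant `"per_household"`:
#' \deqn{A^{trad}_i = \sum_{l:\,d_{il} \le d_0} G(d_{il}, d_0)\,S_l / H_i,}
#' the decay-weighted green area reachable from community i divided by its
#' own households — same units as the 2SFCA score (m² per household) but
#' with no cross-community competition for supply. Variant
#' `"decayed_supply"` omits the household normalisation and returns the
#' decay-weighted reachable area itself.
#'
#' For a lone community the 2SFCA competition term reduces to its own
#' decayed households and the kernel cancels, so 2SFCA yields the full
#' reachable area per household while this baseline keeps the decay: the
#' 2SFCA/baseline ratio is >= 1 for single-community clusters, with
#' equality when the community sits on its green spots (decay weight 1).
#' Cross-community competition is what pushes the ratio below 1.
#'
#' @inheritParams two_step_fca
#' @param variant `"per_household"` (default) or `"decayed_supply"`.
#' @return Numeric vector of baseline accessibility scores, one per
#'   community.
#' @export
traditional_accessibility <- function(communities, greenspaces, d0,
                                      metric = c("haversine", "euclidean"),
                                      variant = c("per_household", "decayed_supply"),
                                      dmatrix = NULL) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  if (nrow(communities) == 0L) stop("no demand points")
  if (nrow(greenspaces) == 0L) return(rep(0, nrow(communities)))
  if (is.null(dmatrix)) {
    dmatrix <- pairwise_distances(communities, greenspaces, metric)
  }
  w <- gaussian_decay(dmatrix, d0)
  supplied <- as.vector(w %*% greenspaces$area_m2)
  switch(variant,
         per_household = supplied / communities$households,
         decayed_supply = supplied)
}

#' City mean accessibility and the 2SFCA/traditional ratio
#'
#' Summarises one city at one radius: mean 2SFCA accessibility (unweighted
#' over communities, matching the "average community accessibility level"
#' convention, plus a household-weighted variant), the mean of the
#' demand-blind baseline, and their ratio. A ratio above 1 means the
#' demand-blind method underestimates real accessibility; below 1, it
#' overestimates it.
#'
#' @param field A `ugs_field` from [two_step_fca()].
#' @param A_trad Numeric vector from [traditional_accessibility()], same
#'   communities and radius.
#' @param city_id City identifier carried into the result.
#' @param weighted If `TRUE`, the ratio uses household-weighted means
#'   instead of unweighted means (default `FALSE`).
#' @return One-row tibble: `city_id`, `radius_m`, `mean_A`, `mean_A_wt`,
#'   `mean_A_trad`, `ratio` (`NA` when the baseline mean is 0).
#' @export
city_ratio <- function(field, A_trad, city_id = NA_character_,
                       weighted = FALSE) {
  stopifnot(inherits(field, "ugs_field"), length(A_trad) == length(field$A))
  h <- field$households
  mean_A <- mean(field$A)
  mean_A_wt <- sum(h * field$A) / sum(h)
  mean_trad <- if (weighted) sum(h * A_trad) / sum(h) else mean(A_trad)
  num <- if (weighted) mean_A_wt else mean_A
  tibble::tibble(
    city_id = city_id, radius_m = field$d0,
    mean_A = mean_A, mean_A_wt = mean_A_wt, mean_A_trad = mean_trad,
    ratio = if (mean_trad > 0) num / mean_trad else NA_real_
  )
}

#' Welch two-sample t-test of a city attribute between ratio groups
#'
#' Unequal-variance (Welch) two-sided t-test, used to compare e.g. total
#' green area or mean house price between cities whose 2SFCA/traditional
#' ratio exceeds 1 and those below 1.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 finite
#'   values.
#' @return One-row tibble: `mean_a`, `mean_b`, `t`, `df`, `p_value`,
#'   `stars` (significance at 0.10/0.05/0.01).
#' @export
welch_t_test <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 finite values")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  tibble::tibble(
    mean_a = mean(values_a), mean_b = mean(values_b),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, stars = p_stars(ht$p.value)
  )
}

p_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}

#' Assign cities to house-price tiers
#'
#' Fixed mode splits mean prices at the given breakpoints into contiguous
#' closed bands, a boundary value going to the lower tier (a breakpoint of
#' 5500 puts price 5500 in tier 1 and 5501 in tier 2). Prices outside
#' `bounds` are assigned to the end tier with a warning. Quantile mode
#' splits into `n_tiers` equal-count tiers instead.
#'
#' @param prices Numeric vector of city mean house prices (yuan/m²).
#' @param breakpoints Ascending interior breakpoints; the default bounds
#'   five conventional bands (up to 5500, 5501-7640, 7641-11038,
#'   11039-23902, above).
#' @param mode `"fixed"` (default) or `"quantile"`.
#' @param bounds Optional overall `c(low, high)` used only to warn about
#'   out-of-range prices in fixed mode.
#' @param n_tiers Number of tiers in quantile mode.
#' @return Integer vector of tier numbers (1 = cheapest).
#' @examples
#' price_tiers(c(5500, 6000, 20000))  # 1, 2, 4
#' @export
price_tiers <- function(prices, breakpoints = c(5500, 7640, 11038, 23902),
                        mode = c("fixed", "quantile"),
                        bounds = NULL, n_tiers = 5) {
  mode <- match.arg(mode)
  if (mode == "quantile") {
    qs <- stats::quantile(prices, probs = seq(0, 1, length.out = n_tiers + 1))
    return(as.integer(cut(prices, breaks = unique(qs), include.lowest = TRUE,
                          right = TRUE)))
  }
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly ascending")
  }
  if (!is.null(bounds)) {
    out <- prices < bounds[1] | prices > bounds[2]
    if (any(out)) {
      warning(sum(out), " price(s) outside [", bounds[1], ", ", bounds[2],
              "]; assigned to end tiers")
    }
  }
  # left-open intervals: a price equal to a breakpoint stays in the lower tier
  findInterval(prices, breakpoints, left.open = TRUE) + 1L
}

#' Per-tier ordinary least squares of Gini on house price
#'
#' Within each price tier (and implicitly one catchment radius), fits
#' `gini ~ price` by OLS across cities and reports the slope, intercept and
#' the two-sided p value of the slope. Tiers with fewer than 3 cities, or
#' with constant price, are flagged and not fitted.
#'
#' @param gini Numeric vector of city Gini coefficients.
#' @param price Numeric vector of city mean house prices, same length.
#' @param tiers Integer tier assignment from [price_tiers()], same length.
#' @param radius_m Radius label carried into the result (optional).
#' @return Tibble with one row per tier: `tier`, `radius_m`, `n`, `slope`,
#'   `intercept`, `p_value`, `stars`, `fitted` (FALSE when degenerate).
#' @export
tier_ols <- function(gini, price, tiers, radius_m = NA_real_) {
  stopifnot(length(gini) == length(price), length(price) == length(tiers))
  ok <- is.finite(gini) & is.finite(price) & !is.na(tiers)
  res <- lapply(sort(unique(tiers[ok])), function(tt) {
    sel <- ok & tiers == tt
    n <- sum(sel)
    if (n < 3 || stats::sd(price[sel]) == 0) {
      return(tibble::tibble(tier = tt, radius_m = radius_m, n = n,
                            slope = NA_real_, intercept = NA_real_,
                            p_value = NA_real_, stars = "", fitted = FALSE))
    }
    fit <- stats::lm(gini[sel] ~ price[sel])
    # a perfect fit is legitimate here (degenerate p value, exact slope)
    cf <- suppressWarnings(summary(fit))$coefficients
    tibble::tibble(tier = tt, radius_m = radius_m, n = n,
                   slope = cf[2, 1], intercept = cf[1, 1],
                   p_value = cf[2, 4], stars = p_stars(cf[2, 4]),
                   fitted = TRUE)
  })
  do.call(rbind, res)
}
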