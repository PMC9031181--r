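#' Run the full accessibility-equity pipeline
#'
#' For every city and every catchment radius: computes 2SFCA accessibility
#' and the demand-blind baseline, the city mean accessibility and their
#' ratio, applies the inclusion rule, and computes the grouped Gini with
#' its inequality classification. City attribute summaries (total green
#' area, mean house price) are attached for the downstream group tests and
#' tier regressions.
#'
#' @param communities Tibble as from [read_communities()] or
#'   [generate_city()]; must contain `city_id`, `id`, `lon`, `lat`,
#'   `households` and (for the price analyses) `price`.
#' @param greenspaces Tibble as from [read_greenspaces()]; `city_id`, `id`,
#'   `lon`, `lat`, `area_m2`.
#' @param config A [run_config()].
#' @return A list of class `ugs_result`: `per_community` (city_id,
#'   community_id, radius_m, A, A_trad), `per_city` (means, ratio, Gini,
#'   level, exclusion flags, green_area_ha, mean_price, n_greenspots) and
#'   `config`.
#' @export
ugs_pipeline <- function(communities, greenspaces, config = run_config()) {
  stopifnot(inherits(config, "ugs_config"))
  if (nrow(communities) == 0L) stop("no communities")
  cities <- unique(communities$city_id)
  per_com <- list()
  per_city <- list()
  for (ct in cities) {
    com <- communities[communities$city_id == ct, ]
    grn <- greenspaces[greenspaces$city_id == ct, , drop = FALSE]
    dmat <- if (nrow(grn) > 0) {
      pairwise_distances(com, grn, config$distance_metric)
    } else NULL
    for (d0 in config$radii_m) {
      field <- withCallingHandlers(
        two_step_fca(com, grn, d0, config$distance_metric, dmatrix = dmat),
        warning = function(w) invokeRestart("muffleWarning"))
      A_trad <- traditional_accessibility(com, grn, d0,
                                          config$distance_metric,
                                          config$traditional_variant,
                                          dmatrix = dmat)
      per_com[[length(per_com) + 1L]] <- tibble::tibble(
        city_id = ct, community_id = field$community_id,
        radius_m = d0, A = field$A, A_trad = A_trad)
      row <- cbind(
        gini_city(field, ct, config$min_communities, config$min_nonzero_share),
        city_ratio(field, A_trad, ct)[, c("mean_A", "mean_A_wt",
                                          "mean_A_trad", "ratio")]
      )
      row$green_area_ha <- sum(grn$area_m2) / 1e4
      row$mean_price <- if ("price" %in% names(com)) mean(com$price) else NA_real_
      row$n_greenspots <- nrow(grn)
      per_city[[length(per_city) + 1L]] <- row
    }
  }
  structure(list(per_community = do.call(rbind, per_com),
                 per_city = tibble::as_tibble(do.call(rbind, per_city)),
                 config = config),
            class = "ugs_result")
}

#' @export
print.ugs_result <- function(x, ...) {
  pc <- x$per_city
  cat(sprintf("<ugs_result> %d cities x %d radii (%s)\n",
              length(unique(pc$city_id)), length(x$config$radii_m),
              x$config$distance_metric))
  for (d0 in x$config$radii_m) {
    s <- pc[pc$radius_m == d0 & !pc$excluded, ]
    cat(sprintf("  d0 = %5g m: mean A %10.2f | mean Gini %.3f | Dangerous %4.1f%% | ratio>1 %4.1f%%\n",
                d0, mean(s$mean_A), mean(s$gini),
                100 * mean(s$level == "Dangerous"),
                100 * mean(s$ratio > 1, na.rm = TRUE)))
  }
  if (any(pc$excluded)) {
    cat(sprintf("  excluded city-radius rows: %d\n", sum(pc$excluded)))
  }
  invisible(x)
}

#' Welch t-tests of city attributes between ratio groups
#'
#' At each radius, splits cities into those with a 2SFCA/traditional ratio
#' above 1 and below 1 and Welch-tests total green area and mean house
#' price between the groups.
#'
#' @param per_city The `per_city` table of a [ugs_pipeline()] result.
#' @return Tibble: `radius_m`, `indicator`, `mean_ratio_lt1`,
#'   `mean_ratio_gt1`, `t`, `p_value`, `stars`, `n_lt1`, `n_gt1` (rows only
#'   where both groups have >= 2 cities).
#' @export
ratio_group_tests <- function(per_city) {
  pc <- per_city[!per_city$excluded & is.finite(per_city$ratio), ]
  out <- list()
  for (d0 in sort(unique(pc$radius_m))) {
    s <- pc[pc$radius_m == d0, ]
    lt <- s[s$ratio < 1, ]
    gt <- s[s$ratio > 1, ]
    if (nrow(lt) < 2 || nrow(gt) < 2) next
    for (ind in c("green_area_ha", "mean_price")) {
      tt <- welch_t_test(lt[[ind]], gt[[ind]])
      out[[length(out) + 1L]] <- tibble::tibble(
        radius_m = d0, indicator = ind,
        mean_ratio_lt1 = tt$mean_a, mean_ratio_gt1 = tt$mean_b,
        t = tt$t, p_value = tt$p_value, stars = tt$stars,
        n_lt1 = nrow(lt), n_gt1 = nrow(gt))
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Per-tier regression of equity on house price
#'
#' Assigns cities to price tiers and, per radius and tier, regresses the
#' city Gini coefficient on mean house price.
#'
#' @param per_city The `per_city` table of a [ugs_pipeline()] result.
#' @param breakpoints Tier breakpoints (yuan/m²); see [price_tiers()].
#' @param mode `"fixed"` or `"quantile"`; quantile mode is the sensible
#'   choice for synthetic data whose price range differs from the default
#'   bands.
#' @param n_tiers Tiers in quantile mode.
#' @return Tibble as [tier_ols()], stacked over radii.
#' @export
price_tier_regression <- function(per_city,
                                  breakpoints = c(5500, 7640, 11038, 23902),
                                  mode = c("fixed", "quantile"), n_tiers = 5) {
  mode <- match.arg(mode)
  pc <- per_city[!per_city$excluded & is.finite(per_city$gini) &
                   is.finite(per_city$mean_price), ]
  out <- list()
  for (d0 in sort(unique(pc$radius_m))) {
    s <- pc[pc$radius_m == d0, ]
    tiers <- price_tiers(s$mean_price, breakpoints, mode, n_tiers = n_tiers)
    out[[length(out) + 1L]] <- tier_ols(s$gini, s$mean_price, tiers, d0)
  }
  do.call(rbind, out)
}
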