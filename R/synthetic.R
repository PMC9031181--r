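#' Synthetic city configuration
#'
#' Generative parameters for one synthetic city, defaulting to the
#' marginals of a typical Chinese prefecture-level city: about 315
#' communities and 33 green spots per city, spot areas lognormal with mean
#' 14.96 ha truncated at 1 ha, and a mean house price around 16,368
#' yuan/m². Coordinates are planar meters on a square of side `extent_m`
#' (use the `"euclidean"` metric downstream).
#'
#' @param n_communities Expected number of communities (Poisson mean when
#'   `fixed_counts = FALSE`, exact count otherwise).
#' @param n_greenspots Expected number of green spots (same convention).
#' @param fixed_counts Use the counts exactly instead of Poisson draws.
#' @param extent_m City square side in meters.
#' @param layout Community layout: `"uniform"`, `"monocentric"` (density
#'   decays exponentially from the center) or `"clustered"` (parent-child
#'   clusters).
#' @param green_cluster Concentration of green spots near a random focus:
#'   0 places them uniformly; larger values tighten the cluster (Gaussian
#'   spread `extent_m / (2 * green_cluster)`).
#' @param spot_area_mean_ha Target mean spot area in hectares (after
#'   truncation at `spot_min_ha`).
#' @param spot_area_sdlog Lognormal log-scale sd of spot areas.
#' @param spot_min_ha Lower truncation of spot areas, hectares.
#' @param households_median,households_sdlog Lognormal parameters for
#'   community household counts (rounded, floored at 1).
#' @param price_base Baseline house price, yuan/m².
#' @param price_gamma Price-green coupling: price multiplier
#'   `exp(price_gamma * z)` where z is the standardized decay-weighted green
#'   supply near the community. 0 decouples price from green proximity.
#' @param price_noise_sd Lognormal noise sd on price.
#' @param coupling_radius_m Radius used to measure green proximity for the
#'   price coupling.
#' @return A list of class `ugs_city_config`.
#' @export
city_config <- function(n_communities = 315,
                        n_greenspots = 33,
                        fixed_counts = FALSE,
                        extent_m = 20000,
                        layout = c("uniform", "monocentric", "clustered"),
                        green_cluster = 0,
                        spot_area_mean_ha = 14.96,
                        spot_area_sdlog = 1.2,
                        spot_min_ha = 1,
                        households_median = 800,
                        households_sdlog = 0.8,
                        price_base = 16368,
                        price_gamma = 0.3,
                        price_noise_sd = 0.2,
                        coupling_radius_m = 2500) {
  layout <- match.arg(layout)
  stopifnot(extent_m > 0, n_communities >= 1, n_greenspots >= 1,
            spot_area_mean_ha >= spot_min_ha, spot_min_ha > 0,
            green_cluster >= 0, price_base > 0, price_noise_sd >= 0)
  structure(as.list(environment()), class = "ugs_city_config")
}

# meanlog of a lognormal truncated below at `lower` whose truncated mean
# equals `target`, given sdlog
trunc_lnorm_meanlog <- function(target, sdlog, lower) {
  tmean <- function(mu) {
    la <- log(lower)
    exp(mu + sdlog^2 / 2) * stats::pnorm((mu + sdlog^2 - la) / sdlog) /
      stats::pnorm((mu - la) / sdlog) - target
  }
  stats::uniroot(tmean, lower = log(target) - 4 * sdlog,
                 upper = log(target) + 1, tol = 1e-10)$root
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  p0 <- stats::plnorm(lower, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p0, 1), meanlog, sdlog)
}

sample_layout <- function(n, extent, layout) {
  clip <- function(v) pmin(pmax(v, 0), extent)
  switch(layout,
    uniform = cbind(stats::runif(n, 0, extent), stats::runif(n, 0, extent)),
    monocentric = {
      r <- stats::rexp(n, rate = 5 / extent)
      th <- stats::runif(n, 0, 2 * pi)
      cbind(clip(extent / 2 + r * cos(th)), clip(extent / 2 + r * sin(th)))
    },
    clustered = {
      n_par <- max(1L, round(n / 40))
      px <- stats::runif(n_par, 0, extent)
      py <- stats::runif(n_par, 0, extent)
      pick <- sample.int(n_par, n, replace = TRUE)
      cbind(clip(stats::rnorm(n, px[pick], extent / 20)),
            clip(stats::rnorm(n, py[pick], extent / 20)))
    })
}

#' Generate one synthetic city
#'
#' Draws community and green-spot point patterns with the configured
#' layout, clustering, size and price structure. House prices couple to
#' green proximity through `price_gamma`: the decay-weighted green supply
#' within `coupling_radius_m` of each community is standardized within the
#' city and enters the price as a lognormal factor. Fully reproducible for
#' a fixed seed, and the output always passes the input filters (areas >= 1
#' ha, complete attributes).
#'
#' @param config A [city_config()].
#' @param seed Integer seed.
#' @param city_id City identifier stamped on every row.
#' @return A list with `communities` and `greenspaces` tibbles in the
#'   column layout of [read_communities()] / [read_greenspaces()], planar
#'   meters.
#' @export
generate_city <- function(config = city_config(), seed = 1L,
                          city_id = "city1") {
  stopifnot(inherits(config, "ugs_city_config"))
  set.seed(seed)
  n_com <- if (config$fixed_counts) config$n_communities else
    max(2L, stats::rpois(1, config$n_communities))
  n_grn <- if (config$fixed_counts) config$n_greenspots else
    max(1L, stats::rpois(1, config$n_greenspots))
  if (config$extent_m^2 < 100 * (n_com + n_grn)) {
    stop("extent too small for the requested point counts")
  }
  xy_com <- sample_layout(n_com, config$extent_m, config$layout)

  xy_grn <- if (config$green_cluster == 0) {
    cbind(stats::runif(n_grn, 0, config$extent_m),
          stats::runif(n_grn, 0, config$extent_m))
  } else {
    fx <- stats::runif(1, 0.25, 0.75) * config$extent_m
    fy <- stats::runif(1, 0.25, 0.75) * config$extent_m
    sd <- config$extent_m / (2 * config$green_cluster)
    cbind(pmin(pmax(stats::rnorm(n_grn, fx, sd), 0), config$extent_m),
          pmin(pmax(stats::rnorm(n_grn, fy, sd), 0), config$extent_m))
  }

  meanlog <- trunc_lnorm_meanlog(config$spot_area_mean_ha,
                                 config$spot_area_sdlog, config$spot_min_ha)
  area_ha <- rlnorm_trunc(n_grn, meanlog, config$spot_area_sdlog,
                          config$spot_min_ha)
  greenspaces <- tibble::tibble(
    city_id = city_id,
    id = sprintf("%s_g%04d", city_id, seq_len(n_grn)),
    lon = xy_grn[, 1], lat = xy_grn[, 2],
    area_m2 = area_ha * 1e4
  )

  households <- pmax(1L, as.integer(round(stats::rlnorm(
    n_com, log(config$households_median), config$households_sdlog))))
  communities <- tibble::tibble(
    city_id = city_id,
    id = sprintf("%s_c%04d", city_id, seq_len(n_com)),
    lon = xy_com[, 1], lat = xy_com[, 2],
    households = households
  )

  # green proximity -> price coupling
  dmat <- pairwise_distances(communities, greenspaces, "euclidean")
  prox <- as.vector(gaussian_decay(dmat, config$coupling_radius_m) %*%
                      greenspaces$area_m2)
  z <- if (stats::sd(prox) > 0) (prox - mean(prox)) / stats::sd(prox) else
    rep(0, n_com)
  communities$price <- config$price_base *
    exp(config$price_gamma * z + stats::rnorm(n_com, 0, config$price_noise_sd))

  list(communities = communities, greenspaces = greenspaces)
}

#' Generate a synthetic multi-city country
#'
#' Draws `n_cities` cities with parameters jittered around a template
#' configuration, optionally injecting degenerate cities whose green spots
#' all lie farther than any catchment radius from every community (their
#' accessibility is identically zero, exercising the city-exclusion rule).
#' Degenerate injection is seeded and the affected city ids are reported.
#'
#' @param n_cities Number of cities.
#' @param template A [city_config()] used as the parameter center.
#' @param seed Integer seed.
#' @param degenerate_prob Probability that a city is made degenerate.
#' @param jitter Lognormal sd of the per-city multiplicative jitter applied
#'   to expected counts and the price base.
#' @param degenerate_offset_m Displacement applied to a degenerate city's
#'   green spots; must exceed the largest analysis radius (default 20,000).
#' @return A list with stacked `communities` and `greenspaces` tibbles and
#'   `degenerate` (character vector of degenerate city ids, also stored as
#'   an attribute on `greenspaces`).
#' @export
generate_country <- function(n_cities, template = city_config(), seed = 1L,
                             degenerate_prob = 0, jitter = 0.2,
                             degenerate_offset_m = 20000) {
  stopifnot(n_cities >= 1)
  set.seed(seed)
  city_seeds <- sample.int(.Machine$integer.max - 1, n_cities)
  degenerate <- stats::runif(n_cities) < degenerate_prob
  # all country-level draws happen before generate_city reseeds the RNG
  jit <- matrix(stats::rlnorm(3 * n_cities, 0, jitter), ncol = 3)
  out <- lapply(seq_len(n_cities), function(i) {
    cfg <- template
    cfg$n_communities <- max(2, round(template$n_communities * jit[i, 1]))
    cfg$n_greenspots <- max(1, round(template$n_greenspots * jit[i, 2]))
    cfg$price_base <- template$price_base * jit[i, 3]
    city <- generate_city(cfg, seed = city_seeds[i],
                          city_id = sprintf("city%03d", i))
    if (degenerate[i]) {
      city$greenspaces$lon <- city$greenspaces$lon +
        template$extent_m + degenerate_offset_m
    }
    city
  })
  communities <- do.call(rbind, lapply(out, `[[`, "communities"))
  greenspaces <- do.call(rbind, lapply(out, `[[`, "greenspaces"))
  degenerate_ids <- sprintf("city%03d", which(degenerate))
  attr(greenspaces, "degenerate") <- degenerate_ids
  list(communities = communities, greenspaces = greenspaces,
       degenerate = degenerate_ids)
}

#' Fixture cities with known inequality structure
#'
#' Small deterministic cities whose equity outcome is known by
#' construction, for exercising the Gini classification:
#' * `"equal"`: `k` identical, mutually isolated spot-community pairs; every
#'   community has the same per-household accessibility, Gini exactly 0.
#' * `"extreme"`: two equal-household communities far apart with all supply
#'   at one of them; Gini exactly 0.5.
#' * `"clustered"`: communities spread uniformly, green spots concentrated
#'   near one focus; Gini lands well above the uniform layout's.
#'
#' @param level `"equal"`, `"clustered"` or `"extreme"`.
#' @param k Number of pairs (equal) or spots (extreme).
#' @param seed Seed for the clustered scenario.
#' @return As [generate_city()]: `communities` + `greenspaces`, planar
#'   meters; pair separation is 30,000 m, so radii up to 10,000 m keep the
#'   constructed isolation.
#' @export
inequality_scenario <- function(level = c("equal", "clustered", "extreme"),
                                k = 6, seed = 1L) {
  level <- match.arg(level)
  if (level == "equal") {
    pos <- 30000 * (seq_len(k) - 1)
    return(list(
      communities = tibble::tibble(
        city_id = "equal", id = sprintf("c%02d", seq_len(k)),
        lon = pos, lat = 0, households = 100L, price = 10000),
      greenspaces = tibble::tibble(
        city_id = "equal", id = sprintf("g%02d", seq_len(k)),
        lon = pos, lat = 0, area_m2 = 1e5)
    ))
  }
  if (level == "extreme") {
    return(list(
      communities = tibble::tibble(
        city_id = "extreme", id = c("c1", "c2"),
        lon = c(0, 30000), lat = 0, households = 100L,
        price = c(20000, 8000)),
      greenspaces = tibble::tibble(
        city_id = "extreme", id = sprintf("g%02d", seq_len(k)),
        lon = 0, lat = 0, area_m2 = 1e5)
    ))
  }
  cfg <- city_config(n_communities = 200, n_greenspots = 25,
                     fixed_counts = TRUE, green_cluster = 5)
  city <- generate_city(cfg, seed = seed, city_id = "clustered")
  city$communities$city_id <- "clustered"
  city
}
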