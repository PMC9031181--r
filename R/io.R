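#' Read community (demand point) data from CSV
#'
#' Reads a CSV of residential communities and applies the
#' attribute-completeness filter: rows missing any required field, or with
#' non-numeric/invalid `households` or `price`, are dropped with a warning
#' reporting the count. Required fields: id, coordinates, households, price;
#' `city_id` defaults to `"city1"` when absent.
#'
#' @param path CSV file path.
#' @param col_map Named character vector mapping required names
#'   (`id`, `lon`, `lat`, `households`, `price`, `city_id`) to the file's
#'   column names. Defaults to identical names.
#' @return A tibble with columns `city_id`, `id`, `lon`, `lat`,
#'   `households` (integer >= 1), `price` (> 0), and attribute `"dropped"`
#'   giving the number of incomplete rows removed.
#' @export
read_communities <- function(path, col_map = NULL) {
  defaults <- c(id = "id", lon = "lon", lat = "lat",
                households = "households", price = "price", city_id = "city_id")
  if (!is.null(col_map)) defaults[names(col_map)] <- col_map
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- defaults[c("id", "lon", "lat", "households", "price")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n0 <- nrow(raw)
  out <- tibble::tibble(
    city_id = if (defaults[["city_id"]] %in% names(raw))
      raw[[defaults[["city_id"]]]] else "city1",
    id = raw[[defaults[["id"]]]],
    lon = suppressWarnings(as.numeric(raw[[defaults[["lon"]]]])),
    lat = suppressWarnings(as.numeric(raw[[defaults[["lat"]]]])),
    households = suppressWarnings(as.numeric(raw[[defaults[["households"]]]])),
    price = suppressWarnings(as.numeric(raw[[defaults[["price"]]]]))
  )
  complete <- !is.na(out$id) & out$id != "" &
    is.finite(out$lon) & is.finite(out$lat) &
    is.finite(out$households) & out$households >= 1 &
    is.finite(out$price) & out$price > 0
  dropped <- n0 - sum(complete)
  if (dropped > 0) {
    warning(dropped, " incomplete community row(s) dropped")
  }
  out <- out[complete, ]
  out$households <- as.integer(round(out$households))
  if (anyDuplicated(paste(out$city_id, out$id))) {
    stop("community ids must be unique within a city")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Read green-space (supply point) data from CSV or GeoJSON
#'
#' Green spaces may come as a CSV of centroids with an area attribute, or as
#' GeoJSON `Point`/`Polygon`/`MultiPolygon` features. Polygons are reduced
#' to centroid plus area; an explicit `area_m2`/`area_ha` property takes
#' precedence over geometric area. Spots smaller than `min_area_ha`
#' hectares are excluded (boundary inclusive: exactly `min_area_ha` is
#' kept). Features without a resolvable area are dropped with a warning.
#'
#' @param path `.csv`, `.geojson` or `.json` file path.
#' @param min_area_ha Minimum spot area in hectares (default 1).
#' @param area_unit For CSV files with an `area` column of unspecified
#'   name: `"m2"` or `"ha"`. CSV columns named `area_m2` or `area_ha` are
#'   self-describing and ignore this.
#' @param planar Set `TRUE` when GeoJSON coordinates are planar meters
#'   (areas/centroids via the shoelace formula) rather than WGS84 degrees
#'   (geodesic areas).
#' @return A tibble with columns `city_id`, `id`, `lon`, `lat`, `area_m2`,
#'   and attribute `"dropped"` (rows removed by the area filter or for
#'   unresolvable area/geometry).
#' @export
read_greenspaces <- function(path, min_area_ha = 1.0,
                             area_unit = c("m2", "ha"), planar = FALSE) {
  area_unit <- match.arg(area_unit)
  ext <- tolower(tools::file_ext(path))
  gs <- if (ext %in% c("geojson", "json")) {
    read_greenspaces_geojson(path, planar)
  } else {
    read_greenspaces_csv(path, area_unit)
  }
  n0 <- nrow(gs) + attr(gs, "unresolved")
  keep <- is.finite(gs$area_m2) & gs$area_m2 >= min_area_ha * 1e4
  out <- gs[keep, ]
  dropped <- n0 - nrow(out)
  if (dropped > attr(gs, "unresolved")) {
    message(sum(!keep), " green spot(s) below ", min_area_ha, " ha excluded")
  }
  attr(out, "dropped") <- dropped
  out
}

read_greenspaces_csv <- function(path, area_unit) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  area_m2 <- if ("area_m2" %in% names(raw)) {
    as.numeric(raw$area_m2)
  } else if ("area_ha" %in% names(raw)) {
    as.numeric(raw$area_ha) * 1e4
  } else if ("area" %in% names(raw)) {
    as.numeric(raw$area) * if (area_unit == "ha") 1e4 else 1
  } else {
    stop("no area column (area_m2, area_ha or area) in ", path)
  }
  out <- tibble::tibble(
    city_id = if ("city_id" %in% names(raw)) as.character(raw$city_id) else "city1",
    id = as.character(raw$id),
    lon = as.numeric(raw$lon), lat = as.numeric(raw$lat),
    area_m2 = area_m2
  )
  bad <- !is.finite(out$area_m2) | !is.finite(out$lon) | !is.finite(out$lat)
  if (any(bad)) warning(sum(bad), " green spot(s) with unresolvable area/coords dropped")
  out <- out[!bad, ]
  attr(out, "unresolved") <- sum(bad)
  out
}

read_greenspaces_geojson <- function(path, planar) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  rows <- lapply(seq_along(feats), function(k) {
    f <- feats[[k]]
    props <- f$properties
    geom <- f$geometry
    id <- as.character(props$id %||% k)
    city <- as.character(props$city_id %||% "city1")
    cen <- geom_centroid(geom, planar)
    area <- if (!is.null(props$area_m2)) {
      as.numeric(props$area_m2)
    } else if (!is.null(props$area_ha)) {
      as.numeric(props$area_ha) * 1e4
    } else {
      geom_area_m2(geom, planar)
    }
    if (is.null(cen) || !is.finite(area)) return(NULL)
    tibble::tibble(city_id = city, id = id, lon = cen[1], lat = cen[2],
                   area_m2 = area)
  })
  bad <- sum(vapply(rows, is.null, logical(1)))
  if (bad > 0) warning(bad, " feature(s) with unresolvable geometry/area dropped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- tibble::tibble(city_id = character(), id = character(),
                          lon = numeric(), lat = numeric(), area_m2 = numeric())
  }
  attr(out, "unresolved") <- bad
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ring_matrix <- function(ring) {
  do.call(rbind, lapply(ring, function(pt) as.numeric(c(pt[[1]], pt[[2]]))))
}

# planar shoelace area; vertices in meters
shoelace_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

shoelace_centroid <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  j <- c(2:n, 1)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cross) / (6 * a), sum((y + y[j]) * cross) / (6 * a))
}

geom_rings <- function(geom) {
  switch(geom$type,
         Polygon = list(geom$coordinates[[1]]),
         MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
         NULL)
}

geom_area_m2 <- function(geom, planar) {
  if (identical(geom$type, "Point")) return(NA_real_)
  rings <- geom_rings(geom)
  if (is.null(rings)) return(NA_real_)
  sum(vapply(rings, function(r) {
    m <- ring_matrix(r)
    if (planar) shoelace_area(m) else geosphere::areaPolygon(m)
  }, numeric(1)))
}

geom_centroid <- function(geom, planar) {
  if (identical(geom$type, "Point"))
    return(c(geom$coordinates[[1]], geom$coordinates[[2]]))
  rings <- geom_rings(geom)
  if (is.null(rings)) return(NULL)
  m <- ring_matrix(rings[[1]])
  if (planar) shoelace_centroid(m) else as.vector(geosphere::centroid(m))
}

#' Analysis configuration
#'
#' Bundles the run parameters: catchment radii, distance metric, the
#' demand-blind baseline variant, price-tier breakpoints, city inclusion
#' thresholds and the random seed.
#'
#' @param radii_m Strictly ascending positive radii in meters.
#' @param distance_metric `"haversine"` (lon/lat degrees) or `"euclidean"`
#'   (planar meters).
#' @param traditional_variant See [traditional_accessibility()].
#' @param price_breakpoints Strictly ascending tier breakpoints (yuan/m²).
#' @param min_communities,min_nonzero_share See [exclude_city()].
#' @param seed Integer seed for any stochastic step.
#' @return A list of class `ugs_config`.
#' @export
run_config <- function(radii_m = c(1000, 2500, 5000, 10000),
                       distance_metric = c("haversine", "euclidean"),
                       traditional_variant = c("per_household", "decayed_supply"),
                       price_breakpoints = c(5500, 7640, 11038, 23902),
                       min_communities = 2,
                       min_nonzero_share = 0,
                       seed = 1L) {
  distance_metric <- match.arg(distance_metric)
  traditional_variant <- match.arg(traditional_variant)
  if (any(radii_m <= 0) || is.unsorted(radii_m, strictly = TRUE)) {
    stop("radii_m must be strictly positive and strictly ascending")
  }
  if (is.unsorted(price_breakpoints, strictly = TRUE)) {
    stop("price_breakpoints must be strictly ascending")
  }
  if (min_nonzero_share < 0 || min_nonzero_share > 1) {
    stop("min_nonzero_share must lie in [0, 1]")
  }
  structure(list(radii_m = radii_m, distance_metric = distance_metric,
                 traditional_variant = traditional_variant,
                 price_breakpoints = price_breakpoints,
                 min_communities = min_communities,
                 min_nonzero_share = min_nonzero_share,
                 seed = as.integer(seed)),
            class = "ugs_config")
}

#' Read an analysis configuration from YAML
#'
#' Any key of [run_config()] may appear in the file; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `ugs_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals[intersect(names(vals), known)])
}

#' Write analysis results to CSV
#'
#' Writes `per_community.csv` (city_id, community_id, radius_m, A) and
#' `per_city.csv` (city_id, radius_m, n_communities, mean_A, mean_A_wt,
#' mean_A_trad, ratio, gini, level, excluded, reason) with a fixed column
#' order, full numeric precision and stable row ordering, so repeated runs
#' on the same inputs are byte-identical.
#'
#' @param per_community Tibble as produced by [ugs_pipeline()]
#'   (`$per_community`).
#' @param per_city Tibble as produced by [ugs_pipeline()] (`$per_city`).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the two file paths.
#' @export
write_results <- function(per_community, per_city, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  com_cols <- c("city_id", "community_id", "radius_m", "A")
  city_cols <- c("city_id", "radius_m", "n_communities", "mean_A", "mean_A_wt",
                 "mean_A_trad", "ratio", "gini", "level", "excluded", "reason")
  per_community <- per_community[do.call(order, per_community[c("city_id", "radius_m", "community_id")]),
                                 com_cols]
  per_city <- per_city[do.call(order, per_city[c("city_id", "radius_m")]), city_cols]
  f1 <- file.path(dir, "per_community.csv")
  f2 <- file.path(dir, "per_city.csv")
  readr::write_csv(per_community, f1)
  readr::write_csv(per_city, f2)
  invisible(c(per_community = f1, per_city = f2))
}
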