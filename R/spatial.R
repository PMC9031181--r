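#' Pairwise demand-supply distances in meters
#'
#' Computes the dense matrix of straight-line distances between demand points
#' (rows) and supply points (columns). Coordinates are interpreted according
#' to `metric`: `"haversine"` treats `lon`/`lat` as WGS84 degrees and returns
#' great-circle distances on a sphere of radius 6,371,000 m; `"euclidean"`
#' treats them as planar meters.
#'
#' @param demand A data frame with numeric columns `lon`, `lat` (demand
#'   points, e.g. communities).
#' @param supply A data frame with numeric columns `lon`, `lat` (supply
#'   points, e.g. green spaces).
#' @param metric `"haversine"` (default) or `"euclidean"`.
#' @return A numeric matrix of nonnegative distances in meters with
#'   `nrow(demand)` rows and `nrow(supply)` columns, with attribute
#'   `"metric"` recording the metric used.
#' @examples
#' d <- data.frame(lon = 0, lat = 0)
#' s <- data.frame(lon = c(0, 1), lat = c(0, 0))
#' pairwise_distances(d, s)  # 0 and ~111 km
#' @export
pairwise_distances <- function(demand, supply,
                               metric = c("haversine", "euclidean")) {
  metric <- match.arg(metric)
  for (df in list(demand, supply)) {
    if (!all(c("lon", "lat") %in% names(df))) {
      stop("demand and supply must both have 'lon' and 'lat' columns")
    }
    if (!all(is.finite(df$lon)) || !all(is.finite(df$lat))) {
      stop("coordinates must be finite")
    }
  }
  dm <- if (metric == "euclidean") {
    dx <- outer(demand$lon, supply$lon, "-")
    dy <- outer(demand$lat, supply$lat, "-")
    sqrt(dx * dx + dy * dy)
  } else {
    geosphere::distm(
      cbind(demand$lon, demand$lat), cbind(supply$lon, supply$lat),
      fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000)
    )
  }
  dm <- matrix(dm, nrow = nrow(demand), ncol = nrow(supply))
  attr(dm, "metric") <- metric
  dm
}

#' Catchment membership at radius d0
#'
#' Returns the indices of points whose distance from a given center is at
#' most `d0` (boundary inclusive). With `axis = "demand"` the center is a
#' supply point (column) and the demand points in its catchment are returned;
#' with `axis = "supply"` the center is a demand point (row) and the
#' reachable supply points are returned.
#'
#' @param dmatrix Distance matrix from [pairwise_distances()].
#' @param center_index Row (axis = "supply") or column (axis = "demand")
#'   index of the catchment center.
#' @param d0 Catchment radius in meters, > 0.
#' @param axis Which side of the matrix to search; see above.
#' @return Integer vector of indices, possibly empty.
#' @export
catchment <- function(dmatrix, center_index, d0,
                      axis = c("supply", "demand")) {
  axis <- match.arg(axis)
  if (!is.numeric(d0) || length(d0) != 1L || d0 <= 0) {
    stop("d0 must be a single positive number")
  }
  d <- if (axis == "supply") dmatrix[center_index, ] else dmatrix[, center_index]
  which(d <= d0)
}

#' Grid-bucket spatial index for planar points
#'
#' Buckets planar points into square grid cells of side `cellsize` so that
#' radius queries only inspect nearby cells. Used as an optional fast path
#' for catchment queries on large point sets; results are identical to the
#' dense-matrix path.
#'
#' @param points Data frame with planar `lon`, `lat` in meters.
#' @param cellsize Cell side in meters (a good default is the query radius).
#' @return An object of class `grid_index`.
#' @seealso [grid_query()]
#' @export
grid_index <- function(points, cellsize) {
  stopifnot(cellsize > 0)
  cx <- floor(points$lon / cellsize)
  cy <- floor(points$lat / cellsize)
  key <- paste(cx, cy, sep = ",")
  structure(
    list(
      cellsize = cellsize,
      x = points$lon, y = points$lat,
      buckets = split(seq_len(nrow(points)), key)
    ),
    class = "grid_index"
  )
}

#' Radius query against a grid index
#'
#' Returns indices of indexed points within distance `r` (inclusive) of
#' `(x, y)`, planar meters. Exact: candidate cells are filtered by true
#' Euclidean distance.
#'
#' @param index A [grid_index()].
#' @param x,y Query point, planar meters.
#' @param r Query radius in meters.
#' @return Integer vector of indices into the original point set.
#' @export
grid_query <- function(index, x, y, r) {
  cs <- index$cellsize
  span <- ceiling(r / cs)
  cx <- floor(x / cs)
  cy <- floor(y / cs)
  keys <- as.vector(outer(
    (cx - span):(cx + span), (cy - span):(cy + span),
    function(a, b) paste(a, b, sep = ",")
  ))
  cand <- unlist(index$buckets[intersect(keys, names(index$buckets))],
                 use.names = FALSE)
  if (length(cand) == 0L) return(integer(0))
  d2 <- (index$x[cand] - x)^2 + (index$y[cand] - y)^2
  sort(cand[d2 <= r * r])
}
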