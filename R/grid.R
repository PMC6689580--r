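#' Construct a monitoring site grid
#'
#' A site grid holds the identifiers and planar coordinates (in kilometres)
#' of the fixed acoustic monitoring stations. Inter-site Euclidean distances
#' derived from these coordinates parameterize the spatial correlation of the
#' trend model, so coordinates must already be projected to a planar system;
#' see [project_coordinates()] for a simple helper.
#'
#' @param site_id vector of unique site labels.
#' @param easting_km,northing_km numeric planar coordinates in kilometres.
#' @return An object of class `site_grid`: a data frame with columns
#'   `site_id`, `easting_km`, `northing_km`.
#' @examples
#' g <- site_grid(1:4, c(0, 1, 0, 1), c(0, 0, 1, 1))
#' site_distances(g)
#' @export
site_grid <- function(site_id, easting_km, northing_km) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id))
    stop("site ids must be unique", call. = FALSE)
  if (length(easting_km) != length(site_id) ||
      length(northing_km) != length(site_id))
    stop("coordinate vectors must match site_id in length", call. = FALSE)
  if (!all(is.finite(easting_km)) || !all(is.finite(northing_km)))
    stop("site coordinates must be finite", call. = FALSE)
  g <- data.frame(site_id = site_id,
                  easting_km = as.numeric(easting_km),
                  northing_km = as.numeric(northing_km),
                  stringsAsFactors = FALSE)
  class(g) <- c("site_grid", "data.frame")
  g
}

#' Pairwise inter-site distance matrix
#'
#' @param grid a [site_grid()].
#' @return symmetric matrix of Euclidean distances in kilometres, with zero
#'   diagonal, dimnames the site ids.
#' @export
site_distances <- function(grid) {
  stopifnot(inherits(grid, "site_grid"))
  h <- as.matrix(stats::dist(cbind(grid$easting_km, grid$northing_km)))
  dimnames(h) <- list(grid$site_id, grid$site_id)
  h
}

#' Project geographic coordinates to planar kilometres
#'
#' Converts longitude/latitude to planar easting/northing in kilometres by an
#' equirectangular projection about the centroid of the points: one degree of
#' latitude is taken as 111.32 km and one degree of longitude as
#' 111.32 * cos(latitude at centroid) km. Over a monitoring grid a few tens
#' of kilometres across the distortion is well below the spatial resolution
#' of the model; for larger extents use a proper projected CRS upstream.
#'
#' @param lon,lat numeric degrees.
#' @return data frame with `easting_km`, `northing_km` (centroid at origin).
#' @export
project_coordinates <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  km_per_deg <- 111.32
  lat0 <- mean(lat)
  data.frame(
    easting_km = (lon - mean(lon)) * km_per_deg * cos(lat0 * pi / 180),
    northing_km = (lat - lat0) * km_per_deg
  )
}

#' @export
print.site_grid <- function(x, ...) {
  cat(sprintf("Site grid: %d sites, extent %.1f x %.1f km\n",
              nrow(x), diff(range(x$easting_km)), diff(range(x$northing_km))))
  NextMethod()
}
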