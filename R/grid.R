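#' Build a regular latitude-longitude grid domain
#'
#' Creates the spatial frame used by every field in the package: a regular
#' lat-lon grid with one row per cell and the true spherical cell area in
#' km\eqn{^2}. Cell areas follow the spherical-quadrilateral formula
#' \eqn{A = R^2 \, \Delta\lambda \, (\sin\phi_N - \sin\phi_S)} with
#' \eqn{R = 6371} km, so area varies with latitude only (cosine weighting):
#' a 0.5\eqn{^\circ} cell is ~3,090 km\eqn{^2} at the equator and ~2,500
#' km\eqn{^2} in the mid-latitudes.
#'
#' @param n_lat,n_lon Number of rows (latitude) and columns (longitude).
#' @param lat0,lon0 Coordinates of the first (south-west) cell centre, degrees.
#' @param resolution Grid spacing in degrees (default 0.5).
#'
#' @return A tibble of class `grid_domain` with columns `cell` (integer id,
#'   row-major from the south-west corner), `row`, `col`, `lat`, `lon`,
#'   `area_km2`, and attributes `n_lat`, `n_lon`, `resolution`.
#' @examples
#' make_grid_domain(2, 3, lat0 = 35, lon0 = 100)
#' @export
make_grid_domain <- function(n_lat, n_lon, lat0 = 35, lon0 = 100,
                             resolution = 0.5) {
  if (n_lat < 1 || n_lon < 1 || n_lat != round(n_lat) || n_lon != round(n_lon))
    abort_afw("`n_lat` and `n_lon` must be positive integers.", "invalid_argument")
  if (resolution <= 0)
    abort_afw("`resolution` must be > 0.", "invalid_argument")

  lat_centers <- lat0 + (seq_len(n_lat) - 1) * resolution
  lon_centers <- lon0 + (seq_len(n_lon) - 1) * resolution
  if (any(abs(lat_centers) + resolution / 2 > 90))
    abort_afw("Grid rows extend beyond the poles.", "invalid_argument")

  r_earth <- 6371 # km
  dlon <- resolution * pi / 180
  lat_n <- (lat_centers + resolution / 2) * pi / 180
  lat_s <- (lat_centers - resolution / 2) * pi / 180
  row_area <- r_earth^2 * dlon * (sin(lat_n) - sin(lat_s))

  out <- tidyr::expand_grid(row = seq_len(n_lat), col = seq_len(n_lon)) |>
    dplyr::mutate(
      cell = dplyr::row_number(),
      lat = lat_centers[.data$row],
      lon = lon_centers[.data$col],
      area_km2 = row_area[.data$row]
    ) |>
    dplyr::select("cell", "row", "col", "lat", "lon", "area_km2")

  attr(out, "n_lat") <- as.integer(n_lat)
  attr(out, "n_lon") <- as.integer(n_lon)
  attr(out, "resolution") <- resolution
  class(out) <- c("grid_domain", class(out))
  out
}

#' Total area of a grid domain
#' @param domain A `grid_domain`.
#' @return Total area in km^2.
#' @export
domain_area <- function(domain) sum(domain$area_km2)
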