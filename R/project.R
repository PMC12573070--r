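#' Project longitude/latitude to planar kilometre coordinates
#'
#' Applies an equirectangular projection about the centroid of the input
#' coordinates: `x = R * dlon * cos(latbar)`, `y = R * dlat` (angles in
#' radians, `R` = 6371 km). Adequate for regional extents of a few thousand
#' kilometres, where Matern ranges are quoted in km; the origin is recorded so
#' the projection is invertible.
#'
#' @param data A data frame with `lon` and `lat` columns (decimal degrees).
#' @param origin Optional `c(lon, lat)` projection origin; defaults to the
#'   centroid of the data.
#' @return The input tibble with `x` and `y` columns (km) appended and the
#'   origin stored in the `"proj_origin"` attribute.
#' @export
project_lonlat <- function(data, origin = NULL) {
  stopifnot(all(c("lon", "lat") %in% names(data)))
  if (is.null(origin)) origin <- c(mean(data$lon), mean(data$lat))
  R_earth <- 6371
  latbar <- origin[2] * pi / 180
  out <- dplyr::mutate(
    as_tibble(data),
    x = R_earth * (.data$lon - origin[1]) * pi / 180 * cos(latbar),
    y = R_earth * (.data$lat - origin[2]) * pi / 180
  )
  attr(out, "proj_origin") <- origin
  out
}

#' Inverse of [project_lonlat()]
#'
#' @param data A data frame with `x`, `y` columns (km).
#' @param origin `c(lon, lat)` origin used in the forward projection.
#' @return Tibble with `lon`, `lat` columns appended.
#' @export
unproject_xy <- function(data, origin) {
  R_earth <- 6371
  latbar <- origin[2] * pi / 180
  dplyr::mutate(
    as_tibble(data),
    lon = origin[1] + .data$x / (R_earth * cos(latbar)) * 180 / pi,
    lat = origin[2] + .data$y / R_earth * 180 / pi
  )
}
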