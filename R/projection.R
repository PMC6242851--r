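#' Azimuthal equidistant projection
#'
#' All internal geometry (tracks, grids, polylines) lives in a local planar
#' coordinate system in kilometres, obtained by an azimuthal equidistant
#' projection on a spherical Earth centred at a reference point (normally the
#' centroid of the dataset's raw fixes). Latitude/longitude are kept only in
#' the raw observation streams.
#'
#' @param lat,lon coordinates in decimal degrees.
#' @param center list or numeric vector with elements `lat` and `lon`, the
#'   projection centre in degrees.
#' @param radius_km spherical Earth radius, km.
#' @return `project_aeqd`: data.frame with columns `x`, `y` (km east/north of
#'   the centre). `unproject_aeqd`: data.frame with columns `lat`, `lon`.
#' @export
project_aeqd <- function(lat, lon, center, radius_km = 6371) {
  stopifnot(all(abs(lat) <= 90))
  d2r <- pi / 180
  la <- lat * d2r; lo <- lon * d2r
  la0 <- center[["lat"]] * d2r; lo0 <- center[["lon"]] * d2r
  cosc <- sin(la0) * sin(la) + cos(la0) * cos(la) * cos(lo - lo0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  # k = c / sin(c), with limit 1 at the centre
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- radius_km * k * cos(la) * sin(lo - lo0)
  y <- radius_km * k * (cos(la0) * sin(la) - sin(la0) * cos(la) * cos(lo - lo0))
  data.frame(x = x, y = y)
}

#' @rdname project_aeqd
#' @param x,y planar coordinates in km.
#' @export
unproject_aeqd <- function(x, y, center, radius_km = 6371) {
  d2r <- pi / 180
  la0 <- center[["lat"]] * d2r; lo0 <- center[["lon"]] * d2r
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / radius_km
  lat <- ifelse(rho < 1e-12, la0,
                asin(cos(c_ang) * sin(la0) + y * sin(c_ang) * cos(la0) / rho))
  lon <- ifelse(rho < 1e-12, lo0,
                lo0 + atan2(x * sin(c_ang),
                            rho * cos(la0) * cos(c_ang) - y * sin(la0) * sin(c_ang)))
  data.frame(lat = lat / d2r, lon = ((lon / d2r + 180) %% 360) - 180)
}

#' Minimum distance from points to a set of polylines
#'
#' Exact minimum Euclidean point-to-segment distance over every segment of
#' every polyline, in the planar km system.
#'
#' @param x,y point coordinates (km), equal length.
#' @param lines a list of polylines, each a matrix/data.frame with columns
#'   `x`, `y` (km) and at least two vertices.
#' @return numeric vector of distances (km), one per point.
#' @export
distance_to_polylines <- function(x, y, lines) {
  if (length(lines) == 0) stop("empty polyline set")
  stopifnot(length(x) == length(y))
  best <- rep(Inf, length(x))
  for (ln in lines) {
    ln <- as.matrix(as.data.frame(ln)[, c("x", "y")])
    if (nrow(ln) < 2) stop("polyline needs at least two vertices")
    for (i in seq_len(nrow(ln) - 1)) {
      ax <- ln[i, 1]; ay <- ln[i, 2]
      bx <- ln[i + 1, 1]; by <- ln[i + 1, 2]
      dx <- bx - ax; dy <- by - ay
      L2 <- dx * dx + dy * dy
      t <- if (L2 == 0) rep(0, length(x)) else
        pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / L2))
      d <- sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
      best <- pmin(best, d)
    }
  }
  best
}
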