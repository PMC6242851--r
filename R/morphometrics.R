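#' Allometric body-mass estimation for bearded seals
#'
#' Predicts body mass from standard length and girth with the power-law
#' model \eqn{B = e^{a} L^{b} G^{c}}, where \eqn{B} is body mass (kg),
#' \eqn{L} standard length (cm) and \eqn{G} axillary girth (cm). The default
#' coefficients are the field calibration used for adult bearded seals in
#' Svalbard: \eqn{a = -8.7167}, \eqn{b = 1.0135}, \eqn{c = 1.7686}.
#'
#' @param length_cm standard length in cm (> 0), vectorised.
#' @param girth_cm girth in cm (> 0), vectorised.
#' @param params list with `intercept_log`, `length_exponent`,
#'   `girth_exponent`; see [mass_equation_params()].
#' @return estimated body mass in kg (full precision; round to the nearest
#'   kg when echoing tag tables).
#' @examples
#' round(estimate_body_mass(198, 171))  # 310
#' @export
estimate_body_mass <- function(length_cm, girth_cm, params = mass_equation_params()) {
  if (any(!is.finite(length_cm)) || any(!is.finite(girth_cm)) ||
      any(length_cm <= 0) || any(girth_cm <= 0))
    stop("length and girth must be positive and finite")
  exp(params$intercept_log) *
    length_cm^params$length_exponent *
    girth_cm^params$girth_exponent
}

#' @rdname estimate_body_mass
#' @param intercept_log,length_exponent,girth_exponent model coefficients.
#' @export
mass_equation_params <- function(intercept_log = -8.7167,
                                 length_exponent = 1.0135,
                                 girth_exponent = 1.7686) {
  if (length_exponent <= 0 || girth_exponent <= 0)
    stop("exponents must be positive")
  list(intercept_log = intercept_log,
       length_exponent = length_exponent,
       girth_exponent = girth_exponent)
}

#' Great-circle (haversine) distance
#'
#' Spherical-Earth distance between two points, used e.g. for the
#' north-south displacement of a travelling seal.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @param radius_km Earth radius in km.
#' @return distance in km.
#' @examples
#' round(great_circle_distance(79.3, 10.9, 76.7, 15.3))  # 306
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  if (any(abs(c(lat1, lat2)) > 90)) stop("latitude outside [-90, 90]")
  d2r <- pi / 180
  a <- sin((lat2 - lat1) * d2r / 2)^2 +
    cos(lat1 * d2r) * cos(lat2 * d2r) * sin((lon2 - lon1) * d2r / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}
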