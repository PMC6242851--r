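#' Regular planar grids and the environment stack
#'
#' Grids are stored on cell centres in the local planar km system:
#' `values[iy, ix]` is the value at `x = xmin + (ix-1)*cell`,
#' `y = ymin + (iy-1)*cell`.
#'
#' @param values numeric matrix, `ny x nx` (rows index y).
#' @param xmin,ymin coordinates (km) of the first cell centre.
#' @param cell cell size, km.
#' @return an object of class `planar_grid`.
#' @export
planar_grid <- function(values, xmin, ymin, cell) {
  values <- as.matrix(values)
  structure(list(values = values, xmin = xmin, ymin = ymin, cell = cell,
                 nx = ncol(values), ny = nrow(values)),
            class = "planar_grid")
}

grid_x <- function(g) g$xmin + (seq_len(g$nx) - 1) * g$cell
grid_y <- function(g) g$ymin + (seq_len(g$ny) - 1) * g$cell

#' Bilinear grid lookup
#'
#' Interpolates a `planar_grid` at arbitrary interior points using the four
#' surrounding cell centres. Exact at cell centres; reproduces any affine
#' surface exactly. Queries outside the centre lattice are an error — the
#' grid is never extrapolated.
#'
#' @param grid a [planar_grid()].
#' @param x,y query coordinates (km), vectorised.
#' @return interpolated values.
#' @export
grid_bilinear <- function(grid, x, y) {
  gx <- grid_x(grid); gy <- grid_y(grid)
  if (any(x < gx[1] - 1e-9 | x > gx[grid$nx] + 1e-9 |
          y < gy[1] - 1e-9 | y > gy[grid$ny] + 1e-9))
    stop("query point outside grid extent")
  fx <- pmin(pmax((x - grid$xmin) / grid$cell, 0), grid$nx - 1)
  fy <- pmin(pmax((y - grid$ymin) / grid$cell, 0), grid$ny - 1)
  ix <- pmin(floor(fx), grid$nx - 2); iy <- pmin(floor(fy), grid$ny - 2)
  if (grid$nx == 1) ix <- rep(0, length(x))
  if (grid$ny == 1) iy <- rep(0, length(y))
  tx <- fx - ix; ty <- fy - iy
  v <- grid$values
  i1 <- cbind(iy + 1, ix + 1); i2 <- cbind(iy + 1, pmin(ix + 2, grid$nx))
  i3 <- cbind(pmin(iy + 2, grid$ny), ix + 1)
  i4 <- cbind(pmin(iy + 2, grid$ny), pmin(ix + 2, grid$nx))
  (1 - tx) * (1 - ty) * v[i1] + tx * (1 - ty) * v[i2] +
    (1 - tx) * ty * v[i3] + tx * ty * v[i4]
}

#' Bathymetric depth at a point
#'
#' Bilinear interpolation of the bathymetry layer (positive-down metres) of
#' an environment stack.
#'
#' @param env an `environment_stack` (see [simulate_environment()]).
#' @param x,y planar coordinates, km.
#' @return depth in m (positive down).
#' @export
bathymetry_at <- function(env, x, y) {
  grid_bilinear(env$bathymetry, x, y)
}

#' Sea-ice concentration category
#'
#' Bins ice concentration into the classes used for habitat summaries:
#' `<=10`, `10-40`, `40-90`, `>90` percent, with a separate `landfast`
#' class that dominates whatever the concentration is. Bins are half-open
#' above 10: \[0,10\], (10,40\], (40,90\], (90,100\].
#'
#' @param concentration percent in \[0, 100\], vectorised.
#' @param landfast logical, vectorised.
#' @return factor with levels `<=10`, `10-40`, `40-90`, `>90`, `landfast`.
#' @export
ice_category <- function(concentration, landfast = FALSE) {
  if (any(!is.finite(concentration)) ||
      any(concentration < 0 | concentration > 100))
    stop("ice concentration must be in [0, 100]")
  n <- max(length(concentration), length(landfast))
  concentration <- rep_len(concentration, n)
  landfast <- rep_len(landfast, n)
  lev <- c("<=10", "10-40", "40-90", ">90", "landfast")
  out <- ifelse(landfast, "landfast",
         ifelse(concentration <= 10, "<=10",
         ifelse(concentration <= 40, "10-40",
         ifelse(concentration <= 90, "40-90", ">90"))))
  factor(out, levels = lev)
}

# Ice field for a given date: nearest dated field in the stack.
ice_field_for_date <- function(env, when) {
  if (is.null(env$ice) || length(env$ice$dates) == 0) return(NULL)
  i <- which.min(abs(as.numeric(as_utc(when)) - as.numeric(env$ice$dates)))
  list(concentration = env$ice$fields[[i]], landfast = env$ice$landfast[[i]])
}
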