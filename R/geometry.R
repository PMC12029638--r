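#' Straight and curved microvessel geometries
#'
#' Builds the voxelised solid mask of a constant-diameter tube aligned with
#' the x axis on an `nx x ny x nz` grid. A site is fluid when its
#' perpendicular distance from the local centreline is below `D/2`; the
#' staircase wall is handled by halfway bounce-back in the solver. The
#' centreline of the curved vessel is a single-period sinusoid in the x-y
#' plane, `y(x) = y0 + A sin(2 pi x / L)`, which keeps the tube x-periodic
#' so re-entrant particles see a continuous wall; `amplitude = 0` reduces
#' exactly to the straight vessel.
#'
#' Cross-section centres sit at `(ny-1)/2`, `(nz-1)/2`; with even `ny`, `nz`
#' these are half-integers, which places the halfway bounce-back wall of the
#' diametral rows exactly at radius `D/2`.
#'
#' @param L vessel length in lattice units (the grid x extent; `nx = L`).
#' @param D inner diameter in lattice units.
#' @param grid optional `c(nx, ny, nz)`; defaults to `c(L, D+4, D+4)`.
#' @param amplitude centreline bend amplitude in lattice units.
#' @return object of class `vessel`: `dims`, `L`, `D`, `amplitude`,
#'   `solid` mask array, and `centerline(x)` returning `cbind(y, z)`.
#' @export
straight_vessel <- function(L, D, grid = NULL) {
  curved_vessel(L, D, amplitude = 0, grid = grid)
}

#' @rdname straight_vessel
#' @export
curved_vessel <- function(L, D, amplitude = 10, grid = NULL) {
  if (is.null(grid)) grid <- c(L, D + 4 + 2 * ceiling(abs(amplitude)), D + 4)
  if (length(grid) != 3) stop("grid must be c(nx, ny, nz)", call. = FALSE)
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2]); nz <- as.integer(grid[3])
  y0 <- (ny - 1) / 2; z0 <- (nz - 1) / 2
  if (D > min(ny, nz))
    stop("vessel diameter does not fit in the grid cross-section", call. = FALSE)
  if (abs(amplitude) + D / 2 > min(y0, ny - 1 - y0) + 0.5)
    stop("curved vessel wall would clip the grid boundary", call. = FALSE)

  centerline <- function(x) {
    cbind(y = y0 + amplitude * sin(2 * pi * x / nx), z = rep(z0, length(x)))
  }
  xs <- 0:(nx - 1); ys <- 0:(ny - 1); zs <- 0:(nz - 1)
  cl <- centerline(xs)
  # distance from per-slice centre; constant circular section at every x
  dy2 <- outer(ys, cl[, "y"], function(y, c) (y - c)^2)   # ny x nx
  dz2 <- (zs - z0)^2
  solid <- array(0L, dim = c(nx, ny, nz))
  R2 <- (D / 2)^2
  for (k in seq_len(nz)) {
    # fluid where dy2 + dz2[k] < R^2 ; note dy2 is ny x nx
    solid[, , k] <- as.integer(t(dy2 + dz2[k]) >= R2)
  }
  structure(list(dims = c(nx, ny, nz), L = nx, D = D, amplitude = amplitude,
                 center = c(y0, z0), centerline = centerline, solid = solid),
            class = "vessel")
}

#' @export
print.vessel <- function(x, ...) {
  cat(sprintf("<vessel> L = %d, D = %g, amplitude = %g, grid %d x %d x %d\n",
              x$L, x$D, x$amplitude, x$dims[1], x$dims[2], x$dims[3]))
  cat(sprintf("  %d fluid sites (%.1f%% of grid)\n", sum(x$solid == 0L),
              100 * mean(x$solid == 0L)))
  invisible(x)
}

#' Analytic Poiseuille profiles
#'
#' Reference solutions for body-force-driven laminar pipe flow: the
#' cylindrical form `u(r) = a/(4 nu) (R^2 - r^2)` as a function of radius,
#' and the identical profile written along a diametral line,
#' `u(y) = a/(4 nu) y (D - y)` with `y` measured from the wall
#' (substitute `r = |y - R|`). Note the latter is *not* the plane-channel
#' (parallel-plate) solution, which is `a/(2 nu) y (D - y)`: the two forms
#' here both describe the circular pipe.
#'
#' @param a axial body acceleration.
#' @param nu kinematic viscosity.
#' @param D pipe diameter.
#' @param y diametral coordinate in `[0, D]`, zero at the wall.
#' @return velocity at `y` (or radius `r`).
#' @export
poiseuille_profile <- function(a, nu, D, y) {
  stopifnot(all(y >= -1e-9), all(y <= D + 1e-9))
  a / (4 * nu) * y * (D - y)
}

#' @rdname poiseuille_profile
#' @param R pipe radius (cylindrical form).
#' @param r radial coordinate in `[0, R]`.
#' @export
poiseuille_profile_cylindrical <- function(a, nu, R, r) {
  a / (4 * nu) * (R^2 - r^2)
}
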