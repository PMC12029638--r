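#' Two-point immersed-boundary kernel
#'
#' The 1-D hat function `phi(r) = 1 - |r|` for `|r| < 1` (else 0); the 3-D
#' discrete delta is the tensor product `phi(x) phi(y) phi(z)`. The kernel
#' is non-negative, sums to one over the two nearest sites per axis
#' (partition of unity), and reproduces linear fields exactly.
#'
#' @param r offset(s) in lattice units.
#' @return kernel weight(s).
#' @export
hat_kernel <- function(r) {
  pmax(1 - abs(r), 0)
}

#' Spread Lagrangian node forces onto the fluid grid
#'
#' Each node force is distributed over its 2 x 2 x 2 surrounding sites with
#' hat-kernel weights; the spread total equals the node total exactly.
#' Periodic axes wrap node support across the boundary.
#'
#' @param positions n x 3 node positions (lattice coordinates, site centres
#'   at integers starting from 0).
#' @param forces n x 3 node forces.
#' @param dims grid dimensions `c(nx, ny, nz)`.
#' @param periodic logical length-3; which axes wrap.
#' @return list of arrays `Fx`, `Fy`, `Fz` (dim = grid).
#' @export
spread_forces <- function(positions, forces, dims,
                          periodic = c(TRUE, TRUE, TRUE)) {
  positions <- .as_points(positions)
  forces <- .as_points(forces)
  stopifnot(nrow(positions) == nrow(forces))
  ncell <- prod(dims)
  Fx <- numeric(ncell); Fy <- numeric(ncell); Fz <- numeric(ncell)
  cpp_spread(positions, forces, Fx, Fy, Fz,
             dims[1], dims[2], dims[3],
             as.integer(periodic[1]), as.integer(periodic[2]),
             as.integer(periodic[3]))
  list(Fx = array(Fx, dims), Fy = array(Fy, dims), Fz = array(Fz, dims))
}

#' Interpolate grid velocity at Lagrangian nodes
#'
#' Hat-kernel (trilinear) interpolation of the fluid velocity; the adjoint
#' of [spread_forces()], so `<spread(F), u>_grid = <F, interp(u)>_nodes`.
#'
#' @param u list with arrays `ux`, `uy`, `uz` (as from [macroscopic()]),
#'   or an `lbm_state`.
#' @param positions n x 3 node positions (lattice coordinates).
#' @param dims grid dimensions; taken from `u` when it is a state.
#' @param periodic logical length-3.
#' @return n x 3 matrix of node velocities.
#' @export
interpolate_velocity <- function(u, positions, dims = NULL,
                                 periodic = c(TRUE, TRUE, TRUE)) {
  positions <- .as_points(positions)
  if (inherits(u, "lbm_state")) {
    dims <- u$dims
    u <- list(ux = u$ux, uy = u$uy, uz = u$uz)
  }
  if (is.null(dims)) dims <- dim(u$ux)
  cpp_interp(as.numeric(u$ux), as.numeric(u$uy), as.numeric(u$uz),
             positions, dims[1], dims[2], dims[3],
             as.integer(periodic[1]), as.integer(periodic[2]),
             as.integer(periodic[3]))
}

.as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Forward-Euler advection of Lagrangian nodes
#'
#' `x(t + dt) = x(t) + u(x, t) dt`, optionally wrapping coordinates
#' periodically (axial wrap models particles re-entering the vessel inlet).
#' Within coupled runs meshes keep unwrapped (continuous) coordinates so
#' membrane elements never tear across the boundary; wrapping there is
#' applied inside the transfer kernels instead.
#'
#' @param positions n x 3 node positions.
#' @param velocities n x 3 node velocities.
#' @param dt time step (lattice units; 1 in coupled runs).
#' @param wrap logical length-3; axes to wrap.
#' @param dims grid dimensions (needed when any `wrap` is TRUE).
#' @return updated n x 3 positions.
#' @export
advect_nodes <- function(positions, velocities, dt = 1,
                         wrap = c(FALSE, FALSE, FALSE), dims = NULL) {
  positions <- .as_points(positions)
  velocities <- .as_points(velocities)
  out <- positions + velocities * dt
  if (any(wrap)) {
    stopifnot(!is.null(dims))
    for (d in which(wrap)) out[, d] <- out[, d] %% dims[d]
  }
  out
}

#' Random non-overlapping particle placement in a vessel
#'
#' Draws particle centres uniformly inside the vessel lumen with wall
#' clearance at least `radius + 1` lattice unit and pairwise centre
#' separation at least the sum of radii plus 1, by seeded rejection
#' sampling (deterministic for a given seed).
#'
#' @param vessel a [straight_vessel()]/[curved_vessel()].
#' @param radii numeric vector, one entry per particle to place.
#' @param seed integer RNG seed.
#' @param max_tries rejection budget per particle.
#' @return n x 3 matrix of centres (lattice coordinates).
#' @export
place_particles <- function(vessel, radii, seed, max_tries = 1e4) {
  stopifnot(all(radii < vessel$D / 2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  centers <- matrix(NA_real_, length(radii), 3)
  for (i in seq_along(radii)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, 0, vessel$L)
      cl <- vessel$centerline(x)
      rmax <- vessel$D / 2 - radii[i] - 1
      # uniform over the admissible disc
      rr <- rmax * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      cand <- c(x, cl[1, "y"] + rr * cos(th), cl[1, "z"] + rr * sin(th))
      if (i > 1) {
        sep <- sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                             matrix(cand, i - 1, 3, byrow = TRUE))^2))
        if (any(sep < radii[seq_len(i - 1)] + radii[i] + 1)) next
      }
      centers[i, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("could not place particle %d after %d trials", i, max_tries),
           call. = FALSE)
  }
  colnames(centers) <- c("x", "y", "z")
  centers
}
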