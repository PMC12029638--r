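#' Create a lattice Boltzmann fluid state
#'
#' Allocates the D3Q19 population field and its derived density/velocity
#' fields on an `nx x ny x nz` grid, initialised at equilibrium for the
#' given density and velocity. The state is an environment (reference
#' semantics) so the stepper can update it in place.
#'
#' Boundary handling: the lattice wraps periodically in all three
#' directions; any solid site intercepts streaming with halfway bounce-back,
#' so walls are defined purely by `solid`. A solid site may carry a wall
#' velocity (moving-plate shear) applied through the Ladd momentum
#' correction.
#'
#' @param dims integer vector `c(nx, ny, nz)`.
#' @param tau relaxation time (> 0.5).
#' @param solid logical/integer array of dim `dims`; `TRUE` marks wall sites.
#' @param rho0 initial density (scalar or array).
#' @param u0 initial velocity: length-3 vector, or `ncell x 3` matrix.
#' @param body_force constant body acceleration (force per unit volume at
#'   unit density), length-3, applied to every fluid site each step.
#' @return environment of class `lbm_state`.
#' @export
create_fluid <- function(dims, tau, solid = NULL, rho0 = 1, u0 = c(0, 0, 0),
                         body_force = c(0, 0, 0)) {
  stopifnot(length(dims) == 3, all(dims >= 1), tau > 0.5)
  ncell <- prod(dims)
  if (is.null(solid)) solid <- array(0L, dim = dims)
  solid <- array(as.integer(solid), dim = dims)
  stopifnot(length(solid) == ncell)

  rho <- rep_len(as.numeric(rho0), ncell)
  if (is.null(dim(u0))) u0 <- matrix(rep(u0, each = ncell), ncol = 3)
  feq <- equilibrium(rho, u0)
  f <- as.numeric(t(feq))          # direction-fastest layout
  st <- new.env(parent = emptyenv())
  st$dims <- as.integer(dims)
  st$tau <- tau
  st$solid <- solid
  st$f <- f
  st$fnew <- numeric(length(f))
  st$rho <- rho
  st$ux <- u0[, 1]; st$uy <- u0[, 2]; st$uz <- u0[, 3]
  st$Fx <- numeric(ncell); st$Fy <- numeric(ncell); st$Fz <- numeric(ncell)
  st$body_force <- as.numeric(body_force)
  st$wall_u <- NULL                # list(wx, wy, wz) if any wall moves
  st$t <- 0L
  class(st) <- "lbm_state"
  st
}

#' @export
print.lbm_state <- function(x, ...) {
  cat(sprintf("<lbm_state> %d x %d x %d grid, tau = %.4g, t = %d\n",
              x$dims[1], x$dims[2], x$dims[3], x$tau, x$t))
  cat(sprintf("  %d fluid / %d solid sites\n",
              sum(x$solid == 0L), sum(x$solid != 0L)))
  invisible(x)
}

#' Assign moving-wall velocities
#'
#' Attaches a velocity to solid sites (zero elsewhere); streaming into those
#' sites reflects with the Ladd correction `2 w_i rho (e_i . u_w)/cs^2`, so
#' the halfway wall moves at `u_w`.
#'
#' @param state an `lbm_state`.
#' @param wx,wy,wz arrays (dim = grid) of wall velocity components.
#' @export
set_wall_velocity <- function(state, wx, wy, wz) {
  ncell <- prod(state$dims)
  stopifnot(length(wx) == ncell, length(wy) == ncell, length(wz) == ncell)
  state$wall_u <- list(wx = as.numeric(wx), wy = as.numeric(wy),
                       wz = as.numeric(wz))
  invisible(state)
}

# internal: resolve the per-site force field = immersed-boundary spread force
# plus the constant body acceleration on fluid sites.
.total_force <- function(state) {
  bf <- state$body_force
  if (all(bf == 0) && all(state$Fx == 0) && all(state$Fy == 0) &&
      all(state$Fz == 0)) {
    return(NULL)
  }
  fluid <- as.numeric(state$solid == 0L)
  list(Fx = state$Fx + bf[1] * fluid,
       Fy = state$Fy + bf[2] * fluid,
       Fz = state$Fz + bf[3] * fluid)
}

#' Advance the fluid by LBGK collide-and-stream steps
#'
#' One cycle per step: macroscopic moments (with half-force velocity
#' correction), BGK relaxation toward equilibrium with the Guo source term,
#' propagation with periodic wrap, and halfway bounce-back at solid sites.
#' Mass is conserved to round-off. The stored `rho`/`ux`/`uy`/`uz` fields
#' correspond to the state *before* the final collision (time t), which is
#' the field the immersed boundary interpolates.
#'
#' @param state an `lbm_state` (modified in place).
#' @param steps number of steps.
#' @param check_every divergence check interval (NaN, `rho <= 0`,
#'   `|u| > 0.3`); step index is reported on failure.
#' @return the state, invisibly.
#' @export
lbm_step <- function(state, steps = 1, check_every = 200) {
  d <- state$dims
  w <- state$wall_u
  empty <- numeric(0)
  for (k in seq_len(steps)) {
    ft <- .total_force(state)
    cpp_lbm_step(state$f, state$fnew,
                 state$rho, state$ux, state$uy, state$uz,
                 state$solid,
                 if (is.null(w)) empty else w$wx,
                 if (is.null(w)) empty else w$wy,
                 if (is.null(w)) empty else w$wz,
                 if (is.null(ft)) empty else ft$Fx,
                 if (is.null(ft)) empty else ft$Fy,
                 if (is.null(ft)) empty else ft$Fz,
                 state$tau, d[1], d[2], d[3])
    tmp <- state$f; state$f <- state$fnew; state$fnew <- tmp
    state$t <- state$t + 1L
    if (k %% check_every == 0L || k == steps) .check_divergence(state)
  }
  invisible(state)
}

.check_divergence <- function(state) {
  fluid <- state$solid == 0L
  umax <- max(abs(state$ux[fluid]), abs(state$uy[fluid]), abs(state$uz[fluid]))
  rmin <- min(state$rho[fluid])
  if (!is.finite(umax) || !is.finite(rmin))
    stop(sprintf("simulation diverged (non-finite fields) at step %d", state$t),
         call. = FALSE)
  if (rmin <= 0)
    stop(sprintf("simulation diverged (rho <= 0) at step %d", state$t),
         call. = FALSE)
  if (umax > 0.3)
    stop(sprintf("simulation diverged (max |u| = %.3g > 0.3) at step %d",
                 umax, state$t), call. = FALSE)
  invisible(TRUE)
}

#' Macroscopic fields of the current populations
#'
#' Recomputes `rho = sum_i f_i` and `u = (sum_i e_i f_i + F/2)/rho` from the
#' stored populations and current force field, refreshing the cached fields.
#'
#' @param state an `lbm_state`.
#' @return list with arrays `rho` and `ux`, `uy`, `uz` (dim = grid).
#' @export
macroscopic <- function(state) {
  d <- state$dims
  w <- state$wall_u
  empty <- numeric(0)
  ft <- .total_force(state)
  cpp_macroscopic(state$f, state$rho, state$ux, state$uy, state$uz,
                  state$solid,
                  if (is.null(w)) empty else w$wx,
                  if (is.null(w)) empty else w$wy,
                  if (is.null(w)) empty else w$wz,
                  if (is.null(ft)) empty else ft$Fx,
                  if (is.null(ft)) empty else ft$Fy,
                  if (is.null(ft)) empty else ft$Fz)
  list(rho = array(state$rho, d),
       ux = array(state$ux, d), uy = array(state$uy, d),
       uz = array(state$uz, d))
}

#' Total mass and momentum over fluid sites
#'
#' Mass is `sum_sites sum_i f_i`; momentum is the bare population moment
#' `sum_sites sum_i e_i f_i` (without the half-force shift), whose per-step
#' change under periodic boundaries equals the applied force impulse.
#'
#' @param state an `lbm_state`.
#' @return `total_mass`: scalar; `total_momentum`: length-3 vector.
#' @export
total_mass <- function(state) {
  fm <- matrix(state$f, nrow = 19)
  sum(fm[, state$solid == 0L])
}

#' @rdname total_mass
#' @export
total_momentum <- function(state) {
  fm <- matrix(state$f, nrow = 19)[, state$solid == 0L, drop = FALSE]
  e <- d3q19()$e
  as.numeric(t(e) %*% rowSums(fm))
}
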