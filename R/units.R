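#' Physical/lattice unit system
#'
#' Defines the bridge between SI quantities and lattice units. The lattice is
#' normalised so that the grid spacing, the time step and the fluid density
#' are all 1 in lattice units; every physical quantity converts through
#' powers of `dx` (m), `dt` (s) and `rho` (kg/m^3).
#'
#' Defaults are the microvessel blood-plasma values used throughout the
#' package: `dx` = 1 um, `dt` = 18 ns, density 1050 kg/m^3, dynamic
#' viscosity 1.2e-3 Pa s, which place the dimensionless lattice viscosity at
#' `nu_lat` = 0.0206 and the relaxation frequency at `omega` = 1.78.
#'
#' @param dx grid spacing in metres per lattice unit.
#' @param dt time step in seconds per lattice step.
#' @param rho fluid density in kg/m^3.
#' @param mu dynamic viscosity in Pa s.
#' @return an object of class `unit_system`.
#' @examples
#' us <- unit_system()
#' lattice_viscosity(us)
#' relaxation_from_viscosity(lattice_viscosity(us))$omega  # 1.78
#' @export
unit_system <- function(dx = 1e-6, dt = 1.8e-8, rho = 1050, mu = 1.2e-3) {
  if (!all(is.finite(c(dx, dt, rho, mu))) || any(c(dx, dt, rho, mu) <= 0))
    stop("invalid unit system: dx, dt, rho and mu must all be positive", call. = FALSE)
  us <- structure(list(dx = dx, dt = dt, rho = rho, mu = mu),
                  class = "unit_system")
  nu <- lattice_viscosity(us)
  if (relaxation_from_viscosity(nu)$tau <= 0.5)
    stop("invalid unit system: lattice viscosity gives tau <= 0.5", call. = FALSE)
  us
}

#' @export
print.unit_system <- function(x, ...) {
  nu <- lattice_viscosity(x)
  rt <- relaxation_from_viscosity(nu)
  cat("<unit_system>\n")
  cat(sprintf("  dx  = %g m,  dt = %g s\n", x$dx, x$dt))
  cat(sprintf("  rho = %g kg/m^3,  mu = %g Pa s\n", x$rho, x$mu))
  cat(sprintf("  lattice nu = %.6g,  tau = %.5g,  omega = %.4g\n",
              nu, rt$tau, rt$omega))
  invisible(x)
}

#' Dimensionless lattice kinematic viscosity
#'
#' `nu_lat = (mu/rho) * dt / dx^2`.
#'
#' @param us a [unit_system()].
#' @return the lattice kinematic viscosity (dimensionless).
#' @export
lattice_viscosity <- function(us) {
  stopifnot(inherits(us, "unit_system"))
  (us$mu / us$rho) * us$dt / us$dx^2
}

#' Relaxation time and frequency from lattice viscosity
#'
#' Inverts `nu = (tau - 1/2) cs^2` with the D3Q19 sound speed `cs^2 = 1/3`
#' (lattice units, `dt = 1`): `tau = 3 nu + 1/2`, `omega = 1/tau`.
#'
#' @param nu_lat dimensionless lattice kinematic viscosity, > 0.
#' @return list with `tau` and `omega` (`omega` lies in (0, 2)).
#' @export
relaxation_from_viscosity <- function(nu_lat) {
  if (!is.finite(nu_lat) || nu_lat <= 0)
    stop("lattice viscosity must be positive", call. = FALSE)
  tau <- 3 * nu_lat + 0.5
  list(tau = tau, omega = 1 / tau)
}

#' Lattice viscosity from relaxation time
#'
#' `nu = (tau - 1/2)/3` in lattice units; inverse of
#' [relaxation_from_viscosity()].
#'
#' @param tau relaxation time, > 1/2.
#' @return dimensionless lattice viscosity.
#' @export
viscosity_from_relaxation <- function(tau) {
  stopifnot(tau > 0.5)
  (tau - 0.5) / 3
}

#' Convert velocities between lattice and physical units
#'
#' `u_phys = u_lat * dx/dt`.
#'
#' @param u_lat,u_phys velocities in lattice / SI (m/s) units.
#' @param us a [unit_system()].
#' @return the converted velocity.
#' @export
to_physical_velocity <- function(u_lat, us) {
  stopifnot(inherits(us, "unit_system"))
  u_lat * us$dx / us$dt
}

#' @rdname to_physical_velocity
#' @export
to_lattice_velocity <- function(u_phys, us) {
  stopifnot(inherits(us, "unit_system"))
  u_phys * us$dt / us$dx
}

#' Convert a physical quantity to lattice units
#'
#' Conversion through the mass/length/time scales of the unit system
#' (mass unit `rho dx^3`, length unit `dx`, time unit `dt`). Supported
#' quantity kinds cover everything the membrane and flow model needs.
#'
#' @param value physical value (SI).
#' @param us a [unit_system()].
#' @param what one of `"length"`, `"time"`, `"velocity"`, `"acceleration"`,
#'   `"force"`, `"energy"`, `"surface_modulus"` (N/m, e.g. shear/area/surface
#'   moduli), `"bending_modulus"` (N m), `"volume_modulus"` (N/m^2),
#'   `"kinematic_viscosity"` (m^2/s), `"dynamic_viscosity"` (Pa s),
#'   `"shear_rate"` (1/s), `"pressure"` (Pa).
#' @return value in lattice units.
#' @export
to_lattice <- function(value, us, what) {
  stopifnot(inherits(us, "unit_system"))
  dx <- us$dx; dt <- us$dt; rho <- us$rho
  scale <- switch(match.arg(what, c(
    "length", "time", "velocity", "acceleration", "force", "energy",
    "surface_modulus", "bending_modulus", "volume_modulus",
    "kinematic_viscosity", "dynamic_viscosity", "shear_rate", "pressure")),
    length = dx,
    time = dt,
    velocity = dx / dt,
    acceleration = dx / dt^2,
    force = rho * dx^4 / dt^2,
    energy = rho * dx^5 / dt^2,
    surface_modulus = rho * dx^3 / dt^2,   # N/m
    bending_modulus = rho * dx^5 / dt^2,   # N m (an energy)
    volume_modulus = rho * dx^2 / dt^2,    # N/m^2
    kinematic_viscosity = dx^2 / dt,
    dynamic_viscosity = rho * dx^2 / dt,
    shear_rate = 1 / dt,
    pressure = rho * dx^2 / dt^2
  )
  value / scale
}

#' @rdname to_lattice
#' @export
to_physical <- function(value, us, what) {
  value / to_lattice(1, us, what)
}

#' Body acceleration driving Poiseuille flow at a target Reynolds number
#'
#' For force-driven pipe flow, `a = 32 nu^2 Re / D^3` with `Re = Um D / nu`
#' and `Um = a D^2 / (32 nu)`. Works in any consistent unit system
#' (SI in, SI out; lattice in, lattice out).
#'
#' @param Re target Reynolds number.
#' @param nu kinematic viscosity.
#' @param D channel diameter.
#' @return the body acceleration.
#' @export
poiseuille_acceleration <- function(Re, nu, D) {
  stopifnot(Re >= 0, nu > 0, D > 0)
  32 * nu^2 * Re / D^3
}

#' Mean velocity and Reynolds number of force-driven pipe flow
#'
#' `Um = a D^2/(32 nu)` (equivalently `dp = rho a L` over a length L) and
#' `Re = Um D / nu`.
#'
#' @param ax body acceleration along the axis.
#' @param D channel diameter.
#' @param nu kinematic viscosity.
#' @return `mean_velocity`: the mean velocity; `reynolds_number`: Re.
#' @export
mean_velocity <- function(ax, D, nu) {
  ax * D^2 / (32 * nu)
}

#' @rdname mean_velocity
#' @param Um mean velocity.
#' @export
reynolds_number <- function(Um, D, nu) {
  Um * D / nu
}
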