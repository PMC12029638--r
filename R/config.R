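#' Default experiment configuration
#'
#' A hierarchical configuration mirroring the microvessel study defaults:
#' fluid (SI plasma properties, grid spacing 1 um, time step 18 ns),
#' geometry (100 x 50 um vessel, straight or curved), particles (RBC and
#' DC species with physical moduli), run control (steps, recording, seed).
#' Configurations are plain lists; [read_config()] loads the same structure
#' from a YAML file, overriding defaults key by key.
#'
#' @return nested list of configuration sections.
#' @export
default_config <- function() {
  list(
    fluid = list(dx = 1e-6, dt = 1.8e-8, rho = 1050, mu = 1.2e-3),
    geometry = list(type = "curved", L = 100, D = 50, amplitude = 10),
    particles = list(
      rbc = list(n = 2, radius = 3.5e-6, faces = 480,
                 params = unclass(rbc_parameters())),
      dc = list(n = 2, radius = 1.5e-6, faces = 120,
                params = unclass(dc_parameters()))
    ),
    run = list(steps = 10000, record_every = 250, snapshot_every = 0,
               seed = 1)
  )
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file; keys present override [default_config()] values.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  .merge_lists(default_config(), usr)
}

.merge_lists <- function(base, over) {
  if (!is.list(over)) return(over)
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
      .merge_lists(base[[k]], over[[k]]) else over[[k]]
  }
  base
}

#' Derived lattice quantities of a configuration
#'
#' Builds the [unit_system()] and the lattice-unit geometry and particle
#' parameters implied by a configuration's physical values (the physical
#' column is the single source of truth; lattice values are always derived).
#'
#' @param config a configuration list.
#' @return list: `us`, `tau`, `omega`, `nu_lat`, and per-species lattice
#'   radii and [membrane_params()].
#' @export
config_lattice <- function(config) {
  fl <- config$fluid
  us <- unit_system(dx = fl$dx, dt = fl$dt, rho = fl$rho, mu = fl$mu)
  nu <- lattice_viscosity(us)
  rt <- relaxation_from_viscosity(nu)
  species <- lapply(config$particles, function(sp) {
    p <- do.call(membrane_params, sp$params)
    list(radius_lat = to_lattice(sp$radius, us, "length"),
         params_lat = to_lattice_params(p, us),
         faces = sp$faces, n = sp$n)
  })
  list(us = us, nu_lat = nu, tau = rt$tau, omega = rt$omega,
       species = species)
}
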