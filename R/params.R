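#' Membrane material parameters
#'
#' The five moduli of the membrane model: Skalak shear (`ks`, N/m) and area
#' dilation (`kalpha`, N/m) moduli, the dihedral bending modulus (`kB`, N m),
#' and the global surface (`kA`, N/m) and volume (`kV`, N/m^2) constraint
#' moduli. Values may be physical (SI) or lattice; conversion happens in
#' [to_lattice_params()].
#'
#' @param ks elastic shear modulus (N/m).
#' @param kalpha area dilation modulus (N/m).
#' @param kB bending modulus (N m).
#' @param kA global surface modulus (N/m).
#' @param kV global volume modulus (N/m^2).
#' @return object of class `membrane_params`.
#' @export
membrane_params <- function(ks, kalpha, kB, kA, kV) {
  p <- list(ks = ks, kalpha = kalpha, kB = kB, kA = kA, kV = kV)
  if (any(vapply(p, function(v) !is.finite(v) || v < 0, logical(1))))
    stop("membrane moduli must be finite and non-negative", call. = FALSE)
  structure(p, class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("<membrane_params>\n")
  cat(sprintf("  ks = %g, kalpha = %g, kB = %g, kA = %g, kV = %g\n",
              x$ks, x$kalpha, x$kB, x$kA, x$kV))
  invisible(x)
}

#' Convert physical membrane parameters to lattice units
#'
#' @param params [membrane_params()] in SI units.
#' @param us a [unit_system()].
#' @return [membrane_params()] in lattice units.
#' @export
to_lattice_params <- function(params, us) {
  stopifnot(inherits(params, "membrane_params"))
  membrane_params(
    ks = to_lattice(params$ks, us, "surface_modulus"),
    kalpha = to_lattice(params$kalpha, us, "surface_modulus"),
    kB = to_lattice(params$kB, us, "bending_modulus"),
    kA = to_lattice(params$kA, us, "surface_modulus"),
    kV = to_lattice(params$kV, us, "volume_modulus")
  )
}

#' Reference membrane parameters for red blood cells and drug carriers
#'
#' Physical (SI) moduli of the two particle species used in the microvessel
#' simulations, and the stiffness-sweep cases for drug carriers spanning
#' eight orders of magnitude in shear modulus. `rbc_parameters()` also
#' carries the nominal RBC radius (3.5 um); drug-carrier radii span
#' 1.3-2.0 um.
#'
#' @return `membrane_params` (SI units) with a `radius` attribute in metres.
#' @export
rbc_parameters <- function() {
  p <- membrane_params(ks = 5.0e-6, kalpha = 2.5e-6, kB = 2.0e-19,
                       kA = 0.5, kV = 1.0e6)
  attr(p, "radius") <- 3.5e-6
  p
}

#' @rdname rbc_parameters
#' @param case `NULL` for the baseline drug carrier, or 1..5 for the
#'   stiffness-sweep cases (1 softest, 5 stiffest).
#' @param radius carrier radius in metres (1.3e-6 to 2.0e-6).
#' @export
dc_parameters <- function(case = NULL, radius = 1.5e-6) {
  tab <- dc_stiffness_cases()
  if (is.null(case)) {
    p <- membrane_params(ks = 1.0, kalpha = 0.1, kB = 1.0e-13,
                         kA = 1.0, kV = 1.0e6)
  } else {
    stopifnot(case %in% seq_len(nrow(tab)))
    r <- tab[case, ]
    p <- membrane_params(ks = r$ks, kalpha = r$kalpha, kB = r$kB,
                         kA = r$kA, kV = r$kV)
  }
  attr(p, "radius") <- radius
  p
}

#' @rdname rbc_parameters
#' @export
dc_stiffness_cases <- function() {
  data.frame(
    case = 1:5,
    ks = c(1e-5, 1e-3, 1.0, 1e1, 1e2),
    kalpha = c(1e-6, 1e-4, 1e-1, 1.0, 1e1),
    kB = c(1e-18, 1e-16, 1e-13, 1e-12, 1e-11),
    kA = c(1e-5, 1e-3, 1.0, 1e1, 1e2),
    kV = c(1e1, 1e3, 1e6, 1e7, 1e8)
  )
}
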