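#' Skalak in-plane strain energy
#'
#' Per face, the principal in-plane stretch ratios `lambda1, lambda2` follow
#' from the 2-D deformation gradient mapping the stored reference triangle
#' to the current one; with strain invariants
#' `I1 = lambda1^2 + lambda2^2 - 2` and `I2 = lambda1^2 lambda2^2 - 1`,
#' the Skalak energy density is
#' `eps_s = ks/12 (I1^2 + 2 I1 - 2 I2) + kalpha/12 I2^2`
#' and `E_S = sum_i eps_s,i A0_i` over the undeformed face areas.
#' `I2` vanishes identically for area-preserving shear
#' (`lambda1 = 1/lambda2`), so only the `ks` term penalises pure shear,
#' while `kalpha` penalises area dilation.
#'
#' @param mesh a [tri_mesh()] with reference data.
#' @param params [membrane_params()] (lattice units).
#' @return list: `energy`, and per-face `I1`, `I2`, `lambda1`, `lambda2`,
#'   `density`.
#' @export
skalak_energy <- function(mesh, params) {
  ref <- mesh$reference
  v <- mesh$vertices; f <- mesh$faces
  a1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  a2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  ri <- ref$rinv
  # columns of the 3x2 deformation map F = [a1 a2] R^-1
  f1 <- a1 * ri[, "r11"] + a2 * ri[, "r21"]
  f2 <- a1 * ri[, "r12"] + a2 * ri[, "r22"]
  g11 <- rowSums(f1^2); g22 <- rowSums(f2^2); g12 <- rowSums(f1 * f2)
  detG <- g11 * g22 - g12^2
  if (any(!is.finite(detG)) || any(detG <= 0)) {
    bad <- which(!is.finite(detG) | detG <= 0)[1]
    stop(sprintf("degenerate face %d in skalak_energy", bad), call. = FALSE)
  }
  I1 <- g11 + g22 - 2
  I2 <- detG - 1
  dens <- params$ks / 12 * (I1^2 + 2 * I1 - 2 * I2) + params$kalpha / 12 * I2^2
  tr <- g11 + g22
  disc <- sqrt(pmax(tr^2 - 4 * detG, 0))
  l1sq <- (tr + disc) / 2
  l2sq <- (tr - disc) / 2
  list(energy = sum(dens * ref$A0_faces),
       I1 = I1, I2 = I2,
       lambda1 = sqrt(l1sq), lambda2 = sqrt(pmax(l2sq, 0)),
       density = dens)
}

#' Dihedral bending energy
#'
#' `E_B = (kB/2) sum_edges tan^2((theta - theta0)/2)` over all adjacent face
#' pairs, with `theta` the signed angle between the outward face normals.
#' The tangent half-angle form grows steeply as a fold approaches a crease
#' (`|theta - theta0| -> pi` raises an error) and reduces to the plain
#' quadratic `(kB/2) sum (theta - theta0)^2` for small deviations; the
#' quadratic itself is selectable with `form = "quadratic"`.
#' Rest angles come from the reference configuration, so a sphere is
#' bending-stress-free while spherical.
#'
#' @param mesh a [tri_mesh()] with reference data.
#' @param kB bending modulus (lattice units).
#' @param form `"tan"` (default) or `"quadratic"`.
#' @return list: `energy`, per-edge `theta`, `theta0`.
#' @export
bending_energy <- function(mesh, kB, form = c("tan", "quadratic")) {
  form <- match.arg(form)
  th <- cpp_dihedral_angles(mesh$vertices, mesh$edges - 1L)
  dth <- th - mesh$reference$theta0
  if (form == "tan") {
    if (any(abs(dth) >= pi - 1e-6))
      stop("bending angle approached the tan singularity (|theta-theta0| -> pi)",
           call. = FALSE)
    e <- 0.5 * kB * sum(tan(dth / 2)^2)
  } else {
    e <- 0.5 * kB * sum(dth^2)
  }
  list(energy = e, theta = th, theta0 = mesh$reference$theta0)
}

#' Global area and volume constraint energies
#'
#' `E_A = kA (A - A0)^2 / (2 A0)` and `E_V = kV (V - V0)^2 / (2 V0)`,
#' the quadratic penalties holding total membrane area and enclosed volume
#' at their rest values (`kA` in N/m, `kV` in N/m^2 physically, so both
#' energies are dimensionally N m).
#'
#' @param mesh a [tri_mesh()] with reference data.
#' @param params [membrane_params()] (lattice units).
#' @return list: `E_A`, `E_V`, current `area` and `volume`.
#' @export
area_volume_energy <- function(mesh, params) {
  ref <- mesh$reference
  A <- mesh_area(mesh)
  V <- if (mesh$closed) mesh_volume(mesh) else 0
  list(E_A = 0.5 * params$kA * (A - ref$A0)^2 / ref$A0,
       E_V = if (mesh$closed && params$kV > 0)
         0.5 * params$kV * (V - ref$V0)^2 / ref$V0 else 0,
       area = A, volume = V)
}

#' Total membrane energy
#'
#' `E = E_S + E_B + E_A + E_V`; zero exactly at the reference configuration.
#'
#' @inheritParams area_volume_energy
#' @param bending_form passed to [bending_energy()].
#' @return list with the four components and `total`.
#' @export
membrane_energy <- function(mesh, params, bending_form = "tan") {
  es <- skalak_energy(mesh, params)$energy
  eb <- if (params$kB > 0)
    bending_energy(mesh, params$kB, bending_form)$energy else 0
  av <- area_volume_energy(mesh, params)
  list(E_S = es, E_B = eb, E_A = av$E_A, E_V = av$E_V,
       total = es + eb + av$E_A + av$E_V)
}

#' Nodal membrane forces
#'
#' Analytic gradient `F(x_n) = -dE/dx_n` of the total membrane energy with
#' respect to every vertex, evaluated in compiled code. Translation
#' invariance of the energy makes the forces sum to zero, and rotation
#' invariance makes the net torque vanish (to round-off).
#'
#' @inheritParams membrane_energy
#' @return list: `forces` (N x 3), energy components `E_S`, `E_B`, `E_A`,
#'   `E_V`, and current `area`, `volume`.
#' @export
membrane_forces <- function(mesh, params, bending_form = "tan") {
  ref <- mesh$reference
  if (is.null(ref)) stop("mesh has no reference state", call. = FALSE)
  cpp_membrane_forces(mesh$vertices, mesh$faces - 1L,
                      ref$rinv, ref$A0_faces,
                      mesh$edges - 1L, ref$theta0,
                      params$ks, params$kalpha,
                      params$kB, as.integer(bending_form == "quadratic"),
                      params$kA, params$kV,
                      ref$A0, ref$V0)
}
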