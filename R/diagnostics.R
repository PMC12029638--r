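# internal: semi-axis estimates from the gyration tensor of the vertex
# cloud restricted to a coordinate plane. For an affine image of a sphere
# the square-rooted eigenvalue ratio equals the semi-axis ratio exactly.
.gyration_radii <- function(vertices, plane = c(1, 2)) {
  v <- scale(vertices[, plane, drop = FALSE], scale = FALSE)
  g <- crossprod(v) / nrow(v)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))  # descending: (A, B) up to a common factor
}

#' Taylor shape parameter of a deformed capsule
#'
#' `D = (A - B)/(A + B)` with `A`, `B` the major and minor semi-axes of the
#' vertex cloud's gyration-tensor ellipse in the shear plane. A sphere gives
#' `D = 0`; an ellipsoid with semi-axes 1.2 and 0.8 in the plane gives 0.2.
#' Note the plane is a fixed lab-frame choice (flow/gradient plane), so this
#' quantity is *not* invariant under arbitrary rigid rotations out of that
#' plane - that is the convention of the shear-flow deformation diagnostic.
#'
#' @param mesh a [tri_mesh()] (or an n x 3 vertex matrix).
#' @param plane length-2 axis pair spanning the shear plane.
#' @return the Taylor parameter in (-1, 1).
#' @export
taylor_parameter <- function(mesh, plane = c(1, 2)) {
  v <- if (inherits(mesh, "tri_mesh")) mesh$vertices else .as_points(mesh)
  ab <- .gyration_radii(v, plane)
  (ab[1] - ab[2]) / (ab[1] + ab[2])
}

#' Normalised time-resolved Taylor parameter
#'
#' `D(t) = (ahat - bhat)/(ahat + bhat)` with `ahat = a/a0`, `bhat = b/b0`
#' the major/minor radii normalised by their undeformed values; zero when
#' the particle keeps its undeformed radii ratio, always in (-1, 1), and
#' sign-flipping when the roles of the two axes swap.
#'
#' @param a,b current major and minor radii.
#' @param a0,b0 undeformed radii (positive).
#' @return normalised Taylor parameter.
#' @export
taylor_parameter_normalized <- function(a, b, a0, b0) {
  stopifnot(a0 > 0, b0 > 0)
  ah <- a / a0; bh <- b / b0
  (ah - bh) / (ah + bh)
}

#' Capillary number
#'
#' `Ca = mu gamma r_p / ks`: the ratio of viscous shear stress to membrane
#' elastic stress. Works in any consistent unit system.
#'
#' @param mu dynamic viscosity.
#' @param gamma shear rate.
#' @param r_p initial particle radius.
#' @param ks membrane elastic shear modulus.
#' @return the capillary number.
#' @export
capillary_number <- function(mu, gamma, r_p, ks) {
  stopifnot(mu > 0, gamma >= 0, r_p > 0, ks > 0)
  mu * gamma * r_p / ks
}

#' Radial distance of a particle from the vessel centreline
#'
#' Euclidean distance, in the cross-sectional (y, z) plane, between the
#' particle centroid and the centreline point at the particle's axial
#' position (axial position taken modulo the vessel length).
#'
#' @param mesh a [tri_mesh()] (or centroid as length-3 vector).
#' @param vessel a [straight_vessel()]/[curved_vessel()].
#' @return distance in lattice units.
#' @export
distance_d <- function(mesh, vessel) {
  cen <- if (inherits(mesh, "tri_mesh")) colMeans(mesh$vertices)
         else as.numeric(mesh)
  cl <- vessel$centerline(cen[1] %% vessel$L)
  unname(sqrt((cen[2] - cl[1, "y"])^2 + (cen[3] - cl[1, "z"])^2))
}

#' Equilibration time of a migration series
#'
#' Detects when the radial distance `d(t)` has settled: the first recorded
#' time after which the trailing-window running mean stays within `tol` of
#' the final trailing-window mean through the end of the series. The window
#' defaults to 20% of the series; `tol` defaults to 2% of `D_vessel/2` when
#' a vessel diameter is supplied, else 2% of the final mean.
#'
#' @param t time stamps.
#' @param d radial distances.
#' @param tol settling band (absolute, same units as `d`).
#' @param window fraction of the series used for the running mean.
#' @param D_vessel optional vessel diameter used for the default `tol`.
#' @return the equilibration time, or `NA` ("not reached").
#' @export
equilibration_time <- function(t, d, tol = NULL, window = 0.2,
                               D_vessel = NULL) {
  stopifnot(length(t) == length(d), length(t) > 2)
  n <- length(d)
  w <- max(2L, as.integer(ceiling(window * n)))
  if (is.null(tol)) {
    tol <- if (!is.null(D_vessel)) 0.02 * D_vessel / 2
           else 0.02 * abs(mean(d[(n - w + 1):n]))
  }
  # trailing means ending at each index >= w
  cs <- cumsum(d)
  idx <- w:n
  tm <- (cs[idx] - c(0, cs)[idx - w + 1]) / w
  target <- tm[length(tm)]
  ok <- abs(tm - target) <= tol
  # first index from which ok holds through the end
  stays <- rev(cumprod(rev(ok))) > 0
  if (!any(stays)) return(NA_real_)
  first <- idx[which(stays)[1]]
  # a plateau shorter than one trailing window is "not reached"
  if (first > n - w + 1) return(NA_real_)
  t[first - w + 1]
}
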