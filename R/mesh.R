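#' Triangulated membrane mesh
#'
#' A closed, consistently oriented triangle mesh with the reference
#' (stress-free) data the membrane energy model needs: per-face undeformed
#' shape matrices and areas, per-edge rest dihedral angles, and the rest
#' total area and volume. Constructors [icosphere()] and [biconcave_mesh()]
#' build the two particle species; [set_reference()] (re)captures the
#' current configuration as the equilibrium state.
#'
#' For a closed orientable triangulation Euler's relation fixes the vertex
#' count at `N = Nf/2 + 2` (icosahedron: 20 faces, 12 vertices), and every
#' edge is shared by exactly two faces.
#'
#' @param vertices N x 3 matrix of positions.
#' @param faces Nf x 3 integer matrix (1-based), counter-clockwise from
#'   outside (signed volume > 0).
#' @param closed assert closed-surface topology (default); disable only for
#'   planar test patches.
#' @return object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, closed = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  m <- structure(list(vertices = vertices, faces = faces,
                      closed = closed, reference = NULL),
                 class = "tri_mesh")
  m$edges <- .build_edges(faces, closed = closed)
  if (closed) {
    if (nrow(vertices) != nrow(faces) / 2 + 2)
      stop("closed triangulation must satisfy N = Nf/2 + 2", call. = FALSE)
    if (mesh_volume(m) <= 0)
      stop("faces must be oriented outward (signed volume > 0)", call. = FALSE)
  }
  set_reference(m)
}

# Edge table: rows (i0, i1, iop1, iop2) 1-based, where face1 = (i0,i1,iop1)
# and face2 = (i0,iop2,i1), both CCW. For open patches boundary edges are
# dropped (they carry no bending).
.build_edges <- function(faces, closed = TRUE) {
  nf <- nrow(faces)
  he_from <- c(faces[, 1], faces[, 2], faces[, 3])
  he_to <- c(faces[, 2], faces[, 3], faces[, 1])
  he_op <- c(faces[, 3], faces[, 1], faces[, 2])
  key <- paste(he_from, he_to)
  twin <- match(paste(he_to, he_from), key)
  if (closed && anyNA(twin))
    stop("mesh is not closed: some edges belong to a single face", call. = FALSE)
  if (any(duplicated(key)))
    stop("non-manifold mesh: duplicated half-edge", call. = FALSE)
  sel <- which(!is.na(twin) & he_from < he_to)
  cbind(i0 = he_from[sel], i1 = he_to[sel],
        iop1 = he_op[sel], iop2 = he_op[twin[sel]])
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces, %d edges%s\n",
              nrow(x$vertices), nrow(x$faces), nrow(x$edges),
              if (x$closed) "" else " (open patch)"))
  cat(sprintf("  area = %.4g, volume = %.4g\n", mesh_area(x),
              if (x$closed) mesh_volume(x) else NA))
  if (!is.null(x$reference))
    cat(sprintf("  reference: A0 = %.4g, V0 = %.4g\n",
                x$reference$A0, x$reference$V0))
  invisible(x)
}

#' Mesh geometry helpers
#'
#' `mesh_face_areas` gives the per-face triangle areas, `mesh_area` their
#' sum, `mesh_volume` the signed enclosed volume (divergence theorem over
#' faces; positive for outward orientation), and `mesh_centroid` the mean
#' vertex position.
#'
#' @param mesh a [tri_mesh()].
#' @return numeric vector/scalar as appropriate.
#' @export
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

#' @rdname mesh_face_areas
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' @rdname mesh_face_areas
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  x1 <- v[f[, 1], , drop = FALSE]
  x2 <- v[f[, 2], , drop = FALSE]
  x3 <- v[f[, 3], , drop = FALSE]
  sum(x1[, 1] * (x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2]) -
      x1[, 2] * (x2[, 1] * x3[, 3] - x2[, 3] * x3[, 1]) +
      x1[, 3] * (x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])) / 6
}

#' @rdname mesh_face_areas
#' @export
mesh_centroid <- function(mesh) colMeans(mesh$vertices)

#' Capture the current configuration as the stress-free reference
#'
#' Stores per-face 2-D shape matrices (inverted, for the deformation
#' gradient), per-face areas, per-edge rest dihedral angles, and the rest
#' total area `A0` and volume `V0`. A mesh is in mechanical equilibrium
#' (zero energy, zero force) exactly at its reference configuration; a
#' sphere therefore keeps its nonzero rest dihedrals and is stress-free
#' while spherical.
#'
#' @param mesh a [tri_mesh()].
#' @return the mesh with its `reference` field populated.
#' @export
set_reference <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  a2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  l1 <- sqrt(rowSums(a1^2))
  if (any(l1 == 0)) stop("degenerate reference face", call. = FALSE)
  t1 <- a1 / l1
  nrm <- cbind(a1[, 2] * a2[, 3] - a1[, 3] * a2[, 2],
               a1[, 3] * a2[, 1] - a1[, 1] * a2[, 3],
               a1[, 1] * a2[, 2] - a1[, 2] * a2[, 1])
  ln <- sqrt(rowSums(nrm^2))
  if (any(ln == 0)) stop("degenerate reference face", call. = FALSE)
  nh <- nrm / ln
  t2 <- cbind(nh[, 2] * t1[, 3] - nh[, 3] * t1[, 2],
              nh[, 3] * t1[, 1] - nh[, 1] * t1[, 3],
              nh[, 1] * t1[, 2] - nh[, 2] * t1[, 1])
  # reference shape matrix R = [[|a1|, a2.t1], [0, a2.t2]]; store its inverse
  r11 <- l1; r12 <- rowSums(a2 * t1); r22 <- rowSums(a2 * t2)
  det <- r11 * r22
  rinv <- cbind(r22 / det, 0, -r12 / det, r11 / det)  # (r11,r21,r12,r22) of R^-1
  colnames(rinv) <- c("r11", "r21", "r12", "r22")

  mesh$reference <- list(
    rinv = rinv,
    A0_faces = ln / 2,
    theta0 = if (nrow(mesh$edges) > 0)
      cpp_dihedral_angles(v, mesh$edges - 1L) else numeric(0),
    A0 = sum(ln / 2),
    V0 = if (mesh$closed) mesh_volume(mesh) else 0
  )
  mesh
}

# nearest admissible face count: 20*4^k, optionally with a 6-fold barycentric
# first split (120*4^k), matching the particle resolutions used in practice.
.icosphere_schedule <- function(target_faces) {
  cand <- c(outer(c(20, 120), 4^(0:6)))
  nf <- cand[which.min(abs(cand - target_faces))]
  hexa <- nf %% 120 == 0 && log(nf / 120, 4) %% 1 == 0
  k <- if (hexa) log(nf / 120, 4) else log(nf / 20, 4)
  list(nf = nf, hexa = hexa, k = as.integer(round(k)))
}

#' Spherical membrane mesh (subdivided icosahedron)
#'
#' Builds a near-uniform triangulation of the sphere by subdividing an
#' icosahedron and projecting onto the sphere. Face counts of the form
#' `20 * 4^k` come from midpoint (4-to-1) subdivision; counts `120 * 4^k`
#' insert one 6-to-1 barycentric split first, which provides the 120- and
#' 480-face resolutions used for drug carriers and red blood cells. The
#' closest admissible count to `target_faces` is used.
#'
#' @param radius sphere radius (lattice units).
#' @param target_faces requested face count.
#' @param center length-3 centre position.
#' @return a [tri_mesh()] with `N = Nf/2 + 2` vertices.
#' @examples
#' m <- icosphere(1, 120)   # 120 faces, 62 vertices
#' mesh_area(m) / (4 * pi)  # ~ 0.98
#' @export
icosphere <- function(radius = 1, target_faces = 320, center = c(0, 0, 0)) {
  sch <- .icosphere_schedule(target_faces)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  if (sch$hexa) {
    sp <- .subdivide_hexa(v, f)
    v <- sp$v; f <- sp$f
    v <- v / sqrt(rowSums(v^2))
  }
  for (i in seq_len(sch$k)) {
    sp <- .subdivide_midpoint(v, f)
    v <- sp$v; f <- sp$f
    v <- v / sqrt(rowSums(v^2))
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  tri_mesh(v, f)
}

# 4-to-1 midpoint subdivision
.subdivide_midpoint <- function(v, f) {
  nf <- nrow(f)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e1 <- ek(f[, 1], f[, 2]); e2 <- ek(f[, 2], f[, 3]); e3 <- ek(f[, 3], f[, 1])
  keys <- unique(c(e1, e2, e3))
  mid_idx <- nrow(v) + seq_along(keys)
  names(mid_idx) <- keys
  ab <- do.call(rbind, strsplit(keys, " "))
  ia <- as.integer(ab[, 1]); ib <- as.integer(ab[, 2])
  vm <- (v[ia, , drop = FALSE] + v[ib, , drop = FALSE]) / 2
  v2 <- rbind(v, vm)
  m1 <- mid_idx[e1]; m2 <- mid_idx[e2]; m3 <- mid_idx[e3]
  f2 <- rbind(
    cbind(f[, 1], m1, m3),
    cbind(f[, 2], m2, m1),
    cbind(f[, 3], m3, m2),
    cbind(m1, m2, m3)
  )
  list(v = v2, f = unname(f2))
}

# 6-to-1 split: edge midpoints + face centroid (icosahedron -> 120 faces)
.subdivide_hexa <- function(v, f) {
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e1 <- ek(f[, 1], f[, 2]); e2 <- ek(f[, 2], f[, 3]); e3 <- ek(f[, 3], f[, 1])
  keys <- unique(c(e1, e2, e3))
  mid_idx <- nrow(v) + seq_along(keys)
  names(mid_idx) <- keys
  ab <- do.call(rbind, strsplit(keys, " "))
  ia <- as.integer(ab[, 1]); ib <- as.integer(ab[, 2])
  vm <- (v[ia, , drop = FALSE] + v[ib, , drop = FALSE]) / 2
  cen_idx <- nrow(v) + length(keys) + seq_len(nrow(f))
  vc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
         v[f[, 3], , drop = FALSE]) / 3
  v2 <- rbind(v, vm, vc)
  m1 <- mid_idx[e1]; m2 <- mid_idx[e2]; m3 <- mid_idx[e3]
  f2 <- rbind(
    cbind(f[, 1], m1, cen_idx), cbind(m1, f[, 2], cen_idx),
    cbind(f[, 2], m2, cen_idx), cbind(m2, f[, 3], cen_idx),
    cbind(f[, 3], m3, cen_idx), cbind(m3, f[, 1], cen_idx)
  )
  list(v = v2, f = unname(f2))
}

#' Biconcave red-blood-cell mesh
#'
#' Projects a unit icosphere onto the classical biconcave discocyte:
#' with `r^2 = x^2 + z^2` on the unit sphere,
#' `x' = R x`, `z' = R z`, and
#' `y' = sign(y) R/2 sqrt(1 - r^2) (C0 + C1 r^2 + C2 r^4)`,
#' using shape constants `C0 = 0.207`, `C1 = 2.003`, `C2 = -1.123`.
#' The dimple half-thickness at the axis is `R C0 / 2` and the rim
#' (r = 1) collapses to `y' = 0`. The scale `R` equals the requested
#' maximum radius, and the resulting mesh volume is taken as the
#' equilibrium volume `V0`.
#'
#' @param radius maximum (rim) radius of the cell, lattice units.
#' @param target_faces face count, as in [icosphere()] (480 typical).
#' @param center length-3 centre position.
#' @param C0,C1,C2 shape constants of the biconcave profile.
#' @return a [tri_mesh()], mirror-symmetric about its `y = center[2]` plane.
#' @export
biconcave_mesh <- function(radius, target_faces = 480, center = c(0, 0, 0),
                           C0 = 0.207, C1 = 2.003, C2 = -1.123) {
  stopifnot(C0 > 0)
  sph <- icosphere(1, target_faces)
  v <- sph$vertices
  r2 <- pmin(v[, 1]^2 + v[, 3]^2, 1)
  prof <- 0.5 * sqrt(1 - r2) * (C0 + C1 * r2 + C2 * r2^2)
  vb <- cbind(radius * v[, 1],
              radius * sign(v[, 2]) * abs(prof),
              radius * v[, 3])
  # equatorial vertices have y = 0 exactly; keep sign convention stable there
  vb <- sweep(vb, 2, center, "+")
  tri_mesh(vb, sph$faces)
}

#' Translate / transform mesh vertices
#'
#' Returns a mesh whose vertices are moved (the reference data is kept, so
#' a rigid translation leaves all energies untouched).
#'
#' @param mesh a [tri_mesh()].
#' @param offset length-3 translation.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}
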