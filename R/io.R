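#' Write fluid fields as a legacy VTK structured-points file
#'
#' ASCII legacy VTK (`STRUCTURED_POINTS`) with density, velocity and
#' (optionally) the body-force field, readable by ParaView and pyvista.
#'
#' @param state an `lbm_state`.
#' @param path output file path (conventionally `.vtk`).
#' @param fields which fields to include.
#' @return the path, invisibly.
#' @export
write_vtk_fields <- function(state, path,
                             fields = c("rho", "u", "force")) {
  d <- state$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "hemolbm fluid snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0", "SPACING 1 1 1",
               sprintf("POINT_DATA %d", prod(d))), con)
  if ("rho" %in% fields) {
    writeLines(c("SCALARS rho double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(state$rho, digits = 9, trim = TRUE, scientific = TRUE), con)
  }
  if ("u" %in% fields) {
    writeLines("VECTORS velocity double", con)
    writeLines(paste(format(state$ux, digits = 9, trim = TRUE),
                     format(state$uy, digits = 9, trim = TRUE),
                     format(state$uz, digits = 9, trim = TRUE)), con)
  }
  if ("force" %in% fields) {
    writeLines("VECTORS force double", con)
    writeLines(paste(format(state$Fx, digits = 9, trim = TRUE),
                     format(state$Fy, digits = 9, trim = TRUE),
                     format(state$Fz, digits = 9, trim = TRUE)), con)
  }
  invisible(path)
}

#' Write a membrane mesh to OFF or legacy VTK polydata
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_mesh_off <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
write_mesh_vtk <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hemolbm membrane mesh",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  invisible(path)
}

#' Read a mesh back from an OFF file
#'
#' @param path OFF file written by [write_mesh_off()].
#' @return a [tri_mesh()].
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  stopifnot(trimws(lines[1]) == "OFF")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vt <- do.call(rbind, lapply(lines[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  ft <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]])))
  stopifnot(all(ft[, 1] == 3))
  tri_mesh(vt, ft[, 2:4] + 1L)
}
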