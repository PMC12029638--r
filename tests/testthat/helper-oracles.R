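# shared helpers: finite-difference energy gradients (the independent oracle
# for the analytic membrane forces) and small perturbed meshes.

fd_energy_gradient <- function(mesh, params, form = "tan", h = 1e-6) {
  v0 <- mesh$vertices
  g <- matrix(0, nrow(v0), 3)
  for (i in seq_len(nrow(v0))) {
    for (d in 1:3) {
      mp <- mesh; mp$vertices[i, d] <- v0[i, d] + h
      mm <- mesh; mm$vertices[i, d] <- v0[i, d] - h
      g[i, d] <- (membrane_energy(mp, params, form)$total -
                  membrane_energy(mm, params, form)$total) / (2 * h)
    }
  }
  g
}

perturbed_icosphere <- function(nf = 20, radius = 1, sd = 0.05, seed = 1) {
  m <- icosphere(radius, nf)
  set.seed(seed)
  m$vertices <- m$vertices + matrix(rnorm(length(m$vertices), sd = sd), ncol = 3)
  m
}

# open two-triangle patch sharing edge (1,2), flat in the x-y plane
flat_hinge <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, -1, 0))
  tri_mesh(v, rbind(c(1, 2, 3), c(2, 1, 4)), closed = FALSE)
}

# fold the hinge: rotate vertex 4 about the shared edge (x axis) by angle phi
folded_hinge <- function(phi) {
  m <- flat_hinge()
  p <- m$vertices[4, ]
  m$vertices[4, ] <- c(p[1], p[2] * cos(phi), -p[2] * sin(phi))
  m
}
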