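pars <- membrane_params(ks = 1, kalpha = 0.5, kB = 0.3, kA = 0.7, kV = 0.9)

test_that("all energies vanish exactly at the reference configuration", {
  for (m in list(icosphere(1, 80), biconcave_mesh(3.5, 480))) {
    en <- membrane_energy(m, pars)
    expect_lt(abs(en$total), 1e-14)
    f <- membrane_forces(m, pars)$forces
    expect_lt(max(abs(f)), 1e-12)
  }
})

test_that("uniform stretch reproduces the hand-computed Skalak invariants", {
  m <- icosphere(1, 80)
  m$vertices <- m$vertices * 1.1
  sk <- skalak_energy(m, pars)
  expect_equal(sk$I1, rep(0.42, 80), tolerance = 1e-12)
  expect_equal(sk$I2, rep(0.4641, 80), tolerance = 1e-12)
  dens <- 1 / 12 * (0.42^2 + 2 * 0.42 - 2 * 0.4641) + 0.5 / 12 * 0.4641^2
  expect_equal(sk$energy, dens * m$reference$A0, tolerance = 1e-12)
  # principal-stretch recovery loses half the digits to cancellation when
  # the stretches coincide
  expect_equal(sk$lambda1, rep(1.1, 80), tolerance = 1e-7)
})

test_that("area-preserving shear is penalised by ks only", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- tri_mesh(v, rbind(c(1, 2, 3)), closed = FALSE)
  lam <- 1.3
  m$vertices <- v %*% diag(c(lam, 1 / lam, 1))
  sk_only <- skalak_energy(m, membrane_params(1, 0, 0, 0, 0))
  expect_equal(sk_only$I2, 0, tolerance = 1e-12)
  expect_equal(sort(c(sk_only$lambda1, sk_only$lambda2)),
               sort(c(lam, 1 / lam)), tolerance = 1e-12)
  # the kalpha term contributes nothing here
  sk_full <- skalak_energy(m, membrane_params(1, 10, 0, 0, 0))
  expect_equal(sk_full$energy, sk_only$energy, tolerance = 1e-12)
})

test_that("a quarter-circle fold carries bending energy kB/2 tan^2(pi/4)", {
  m <- folded_hinge(pi / 2)
  be <- bending_energy(m, kB = 2)
  expect_equal(abs(be$theta - be$theta0), pi / 2, tolerance = 1e-12)
  expect_equal(be$energy, 2 / 2 * tan(pi / 4)^2, tolerance = 1e-12)
  bq <- bending_energy(m, kB = 2, form = "quadratic")
  expect_equal(bq$energy, (pi / 2)^2, tolerance = 1e-12)
  # near-crease folds hit the tangent singularity guard
  expect_error(bending_energy(folded_hinge(pi - 1e-9), 1), "singularity")
})

test_that("bending energy is invariant under rigid rotation", {
  m <- icosphere(1, 80)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m$vertices <- m$vertices %*% rot
  expect_lt(bending_energy(m, 1)$energy, 1e-20)
})

test_that("global area and volume penalties are the dimensional quadratics", {
  m <- icosphere(1, 80)
  s <- 1.1
  m$vertices <- m$vertices * s
  av <- area_volume_energy(m, pars)
  A0 <- m$reference$A0; V0 <- m$reference$V0
  expect_equal(av$E_A, 0.5 * 0.7 * (s^2 * A0 - A0)^2 / A0, tolerance = 1e-12)
  expect_equal(av$E_V, 0.5 * 0.9 * (s^3 * V0 - V0)^2 / V0, tolerance = 1e-12)
  # quadratic: doubling the relative volume deviation quadruples E_V
  m2 <- icosphere(1, 80)
  dev1 <- 0.02
  s1 <- (1 + dev1)^(1 / 3); s2 <- (1 + 2 * dev1)^(1 / 3)
  m2$vertices <- m2$vertices * s1
  e1 <- area_volume_energy(m2, membrane_params(0, 0, 0, 0, 1))$E_V
  m2$vertices <- m2$vertices * (s2 / s1)
  e2 <- area_volume_energy(m2, membrane_params(0, 0, 0, 0, 1))$E_V
  expect_equal(e2 / e1, 4, tolerance = 1e-9)
})

test_that("analytic forces match the finite-difference oracle per term", {
  terms <- list(skalak = membrane_params(1, 0.5, 0, 0, 0),
                bending = membrane_params(0, 0, 1, 0, 0),
                area = membrane_params(0, 0, 0, 1, 0),
                volume = membrane_params(0, 0, 0, 0, 1),
                combined = pars)
  for (nf in c(20, 80)) {
    m <- perturbed_icosphere(nf, seed = nf)
    for (nm in names(terms)) {
      fa <- membrane_forces(m, terms[[nm]])$forces
      fd <- -fd_energy_gradient(m, terms[[nm]])
      expect_lt(max(abs(fa - fd)) / max(abs(fd)), 1e-5,
                label = sprintf("%s term, %d faces", nm, nf))
    }
  }
})

test_that("every energy term exerts zero net force and torque", {
  m <- perturbed_icosphere(80, seed = 5)
  for (p in list(membrane_params(1, 0.5, 0, 0, 0),
                 membrane_params(0, 0, 1, 0, 0),
                 membrane_params(0, 0, 0, 1, 0),
                 membrane_params(0, 0, 0, 0, 1))) {
    f <- membrane_forces(m, p)$forces
    scale <- max(abs(f))
    expect_lt(max(abs(colSums(f))), 1e-10 * scale)
    tq <- colSums(cbind(
      m$vertices[, 2] * f[, 3] - m$vertices[, 3] * f[, 2],
      m$vertices[, 3] * f[, 1] - m$vertices[, 1] * f[, 3],
      m$vertices[, 1] * f[, 2] - m$vertices[, 2] * f[, 1]))
    expect_lt(max(abs(tq)), 1e-9 * scale)
  }
})

test_that("an inflated sphere is pushed inward by the volume constraint", {
  m <- icosphere(1, 80)
  m$vertices <- m$vertices * 1.05
  f <- membrane_forces(m, membrane_params(0, 0, 0, 0, 1))$forces
  outward <- m$vertices / sqrt(rowSums(m$vertices^2))
  expect_true(all(rowSums(f * outward) < 0))
})

test_that("overdamped relaxation of a perturbed capsule decreases energy", {
  m <- perturbed_icosphere(80, sd = 0.04, seed = 11)
  e_prev <- membrane_energy(m, pars)$total
  for (k in 1:50) {
    f <- membrane_forces(m, pars)$forces
    m$vertices <- m$vertices + 0.02 * f
    e <- membrane_energy(m, pars)$total
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
  expect_lt(e_prev, 0.05 * membrane_energy(perturbed_icosphere(80, sd = 0.04,
                                                               seed = 11),
                                           pars)$total)
})

test_that("degenerate faces are reported by index", {
  m <- icosphere(1, 20)
  bad <- m
  bad$vertices[m$faces[7, 2], ] <- bad$vertices[m$faces[7, 1], ]
  expect_error(skalak_energy(bad, pars), "face")
  expect_error(membrane_forces(bad, pars), "face")
})
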