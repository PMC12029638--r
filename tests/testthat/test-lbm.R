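test_that("uniform rest fluid is an exact fixed point", {
  fl <- create_fluid(c(6, 6, 6), tau = 0.8)
  f0 <- fl$f
  lbm_step(fl, 10)
  expect_identical(fl$f, f0)
})

test_that("mass is conserved to round-off with periodic and wall boundaries", {
  set.seed(3)
  n <- c(10, 8, 8)
  solid <- array(0L, n); solid[, , c(1, n[3])] <- 1L
  u0 <- matrix(runif(prod(n) * 3, -0.02, 0.02), ncol = 3)
  fl <- create_fluid(n, tau = 0.7, solid = solid, u0 = u0)
  m0 <- total_mass(fl)
  for (k in 1:10) {
    lbm_step(fl, 1)
    expect_lt(abs(total_mass(fl) - m0) / m0, 1e-12)
  }
})

test_that("a uniform body force accelerates the fluid by exactly a per step", {
  ax <- 2.5e-5
  fl <- create_fluid(c(6, 6, 6), tau = 0.9, body_force = c(ax, 0, 0))
  lbm_step(fl, 30)
  u30 <- mean(fl$ux)
  lbm_step(fl, 1)
  expect_equal(mean(fl$ux) - u30, ax, tolerance = 1e-10)
  expect_equal(sd(fl$ux), 0)
})

test_that("macroscopic moments include the half-force velocity shift", {
  fl <- create_fluid(c(4, 4, 4), tau = 1, rho0 = 1.05, u0 = c(0.03, -0.01, 0))
  mac <- macroscopic(fl)
  expect_equal(mean(mac$rho), 1.05)
  expect_equal(mean(mac$ux), 0.03)
  expect_equal(mean(mac$uy), -0.01)
  # populations at rest-weights plus a force field: u = F/(2 rho)
  eps <- 1e-3
  fl2 <- create_fluid(c(4, 4, 4), tau = 1)
  fl2$Fx[] <- 2 * eps
  mac2 <- macroscopic(fl2)
  expect_equal(mean(mac2$ux), eps)
})

test_that("rest fluid beside a wall stays at rest and walls enforce no slip", {
  n <- c(6, 6, 10)
  solid <- array(0L, n); solid[, , c(1, n[3])] <- 1L
  fl <- create_fluid(n, tau = 0.8, solid = solid)
  f0 <- fl$f
  lbm_step(fl, 20)
  expect_identical(fl$f, f0)
})

test_that("moving plates drive an exact linear Couette profile", {
  n <- 16
  solid <- array(0L, c(4, 4, n)); solid[, , c(1, n)] <- 1L
  wx <- array(0, c(4, 4, n)); wx[, , 1] <- -0.04; wx[, , n] <- 0.04
  fl <- create_fluid(c(4, 4, n), tau = 0.8, solid = solid)
  set_wall_velocity(fl, wx, wx * 0, wx * 0)
  lbm_step(fl, 2500)
  macroscopic(fl)
  prof <- array(fl$ux, c(4, 4, n))[1, 1, 2:(n - 1)]
  lin <- -0.04 + 0.08 * ((1:(n - 2)) - 0.5) / (n - 2)
  expect_equal(prof, lin, tolerance = 1e-10)
})

test_that("forced plane channel converges to the parallel-plate solution", {
  n <- 22; tau <- 1; a <- 1e-5
  solid <- array(0L, c(4, 4, n)); solid[, , c(1, n)] <- 1L
  fl <- create_fluid(c(4, 4, n), tau = tau, solid = solid,
                     body_force = c(a, 0, 0))
  lbm_step(fl, 6000)
  macroscopic(fl)
  prof <- array(fl$ux, c(4, 4, n))[1, 1, 2:(n - 1)]
  D <- n - 2; nu <- viscosity_from_relaxation(tau)
  y <- (1:(n - 2)) - 0.5
  ana <- a / (2 * nu) * y * (D - y)    # plane-channel profile
  expect_lt(sqrt(sum((prof - ana)^2) / sum(ana^2)), 0.01)
})

test_that("shear-wave decay recovers the nominal viscosity within 2%", {
  nz <- 32; tau <- 0.7
  u0x <- array(0, c(2, 2, nz))
  for (k in 1:nz) u0x[, , k] <- 1e-4 * sin(2 * pi * (k - 1) / nz)
  fl <- create_fluid(c(2, 2, nz), tau = tau,
                     u0 = cbind(as.numeric(u0x), 0, 0))
  amp0 <- max(abs(fl$ux))
  steps <- 400
  lbm_step(fl, steps)
  macroscopic(fl)
  nu_meas <- -log(max(abs(fl$ux)) / amp0) / (steps * (2 * pi / nz)^2)
  expect_equal(nu_meas, viscosity_from_relaxation(tau), tolerance = 0.02)
})

test_that("divergence is reported with the failing step", {
  fl <- create_fluid(c(6, 6, 6), tau = 0.51, body_force = c(0.05, 0, 0))
  expect_error(lbm_step(fl, 500), "diverged.*step")
})
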