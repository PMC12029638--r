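test_that("a particle-free coupled step reduces exactly to the bare solver", {
  n <- c(10, 8, 8)
  mk <- function() create_fluid(n, tau = 0.9, body_force = c(1e-5, 0, 0))
  fl1 <- mk(); fl2 <- mk()
  sim <- simulation(fl1)
  coupled_step(sim, 25)
  lbm_step(fl2, 25)
  expect_identical(fl1$f, fl2$f)
})

test_that("momentum change per step equals the imposed force impulse", {
  n <- c(12, 12, 12)
  ax <- 1e-5
  fl <- create_fluid(n, tau = 0.8, body_force = c(ax, 0, 0))
  mesh <- icosphere(3, 80, center = c(5.5, 5.5, 5.5))
  mesh$vertices <- sweep(mesh$vertices, 2, c(5.5, 5.5, 5.5)) * 1.06 +
    rep(c(5.5, 5.5, 5.5), each = nrow(mesh$vertices))   # pre-strained
  sim <- simulation(fl, list(mesh),
                    list(membrane_params(0.02, 0.01, 1e-3, 0.05, 0.05)))
  coupled_step(sim, 3)    # past initialisation transients
  f_impulse <- ax * prod(n)           # membrane forces sum to zero
  for (k in 1:5) {
    p0 <- total_momentum(fl)
    coupled_step(sim, 1)
    dp <- total_momentum(fl) - p0
    expect_equal(dp[1], f_impulse, tolerance = 1e-8)
    expect_lt(max(abs(dp[2:3])) / f_impulse, 1e-8)
  }
})

test_that("a capsule at the centre of symmetric channel flow stays centred", {
  vs <- straight_vessel(16, 10, grid = c(16, 14, 14))
  a <- 2e-5
  fl <- create_fluid(vs$dims, tau = 1, solid = vs$solid,
                     body_force = c(a, 0, 0))
  cen0 <- c(7.5, vs$center[1], vs$center[2])
  mesh <- icosphere(2.5, 80, center = cen0)
  # near-rigid limit via membrane sub-iterations
  sim <- simulation(fl, list(mesh),
                    list(membrane_params(0.1, 0.05, 1e-3, 0.2, 0.5)),
                    substeps = 10, mobility = 0.3)
  coupled_step(sim, 1000)
  cen <- colMeans(sim$meshes[[1]]$vertices)
  expect_lt(max(abs(cen[2:3] - cen0[2:3])), 1e-3)
})

test_that("repulsion guard keeps approaching particles apart and conserves momentum", {
  n <- c(16, 12, 12)
  fl <- create_fluid(n, tau = 1)
  m1 <- icosphere(2, 80, center = c(6, 5.5, 5.5))
  m2 <- icosphere(2, 80, center = c(10.4, 5.5, 5.5))   # gap 0.4 < 1.5
  pp <- membrane_params(0.05, 0.02, 0, 0.1, 0.2)
  sim <- simulation(fl, list(m1, m2), list(pp, pp),
                    repulsion = list(strength = 0.1, gap = 1.5))
  fr <- hemolbm:::.repulsion_forces(sim)
  expect_false(is.null(fr))
  # equal and opposite totals, directed apart along x
  expect_equal(colSums(fr[[1]]), -colSums(fr[[2]]), tolerance = 1e-14)
  expect_lt(colSums(fr[[1]])[1], 0)
  coupled_step(sim, 50)
  c1 <- colMeans(sim$meshes[[1]]$vertices)
  c2 <- colMeans(sim$meshes[[2]]$vertices)
  expect_gte(c2[1] - c1[1], 4.4 - 0.2)   # not driven into overlap
})
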