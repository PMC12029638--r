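test_that("hat kernel: support, positivity, partition of unity", {
  expect_equal(hat_kernel(0), 1)
  expect_equal(hat_kernel(c(-1, 1, 2.5)), c(0, 0, 0))
  r <- runif(50)
  expect_true(all(hat_kernel(r) >= 0))
  expect_equal(hat_kernel(r) + hat_kernel(r - 1), rep(1, 50))
})

test_that("spreading puts forces where the kernel says", {
  dims <- c(8, 8, 8)
  # node exactly on a site: everything lands there
  sp <- spread_forces(c(2, 3, 4), c(1, -2, 0.5), dims)
  expect_equal(sp$Fx[3, 4, 5], 1)
  expect_equal(sum(sp$Fx != 0), 1)
  expect_equal(sp$Fy[3, 4, 5], -2)
  # cell-centred node: 8 equal shares
  sp <- spread_forces(c(2.5, 3.5, 4.5), c(1, 0, 0), dims)
  expect_equal(sort(unique(round(as.numeric(sp$Fx), 12))), c(0, 0.125))
  expect_equal(sum(sp$Fx == 0.125), 8)
})

test_that("spread total equals node total for random clouds (incl. wrap)", {
  set.seed(8)
  dims <- c(10, 9, 8)
  pos <- cbind(runif(200, -2, 12), runif(200, 0, 9), runif(200, 0, 8))
  frc <- matrix(rnorm(600), ncol = 3)
  sp <- spread_forces(pos, frc, dims)
  expect_equal(sum(sp$Fx), sum(frc[, 1]), tolerance = 1e-13)
  expect_equal(sum(sp$Fy), sum(frc[, 2]), tolerance = 1e-13)
  expect_equal(sum(sp$Fz), sum(frc[, 3]), tolerance = 1e-13)
})

test_that("interpolation reproduces uniform and linear fields exactly", {
  dims <- c(10, 10, 10)
  ii <- array(rep(0:9, times = 100), dims)                  # x index field
  jj <- array(rep(rep(0:9, each = 10), 10), dims)           # y index field
  set.seed(9)
  pos <- cbind(runif(40, 1, 8), runif(40, 1, 8), runif(40, 1, 8))
  u_uni <- list(ux = ii * 0 + 0.7, uy = ii * 0 - 0.2, uz = ii * 0)
  vn <- interpolate_velocity(u_uni, pos, dims)
  expect_equal(vn[, 1], rep(0.7, 40))
  expect_equal(vn[, 2], rep(-0.2, 40))
  gam <- 0.3
  u_lin <- list(ux = gam * jj, uy = ii * 0, uz = ii * 0)
  vn <- interpolate_velocity(u_lin, pos, dims)
  expect_equal(vn[, 1], gam * pos[, 2], tolerance = 1e-13)
})

test_that("spreading and interpolation are adjoint", {
  set.seed(10)
  dims <- c(7, 8, 9)
  pos <- cbind(runif(30, 0, 7), runif(30, 0, 8), runif(30, 0, 9))
  frc <- matrix(rnorm(90), ncol = 3)
  u <- list(ux = array(rnorm(prod(dims)), dims),
            uy = array(rnorm(prod(dims)), dims),
            uz = array(rnorm(prod(dims)), dims))
  sp <- spread_forces(pos, frc, dims)
  lhs <- sum(sp$Fx * u$ux) + sum(sp$Fy * u$uy) + sum(sp$Fz * u$uz)
  rhs <- sum(frc * interpolate_velocity(u, pos, dims))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("node advection is forward Euler with periodic wrap", {
  pos <- rbind(c(1, 2, 3), c(47.5, 2, 3))
  vel <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(advect_nodes(pos, vel * 0, dt = 1), pos)
  out <- advect_nodes(pos, vel, dt = 1, wrap = c(TRUE, FALSE, FALSE),
                      dims = c(48, 24, 24))
  expect_equal(out[2, 1], 0.5)
  # k uniform steps displace by k u dt
  p <- matrix(c(5, 5, 5), 1)
  for (k in 1:7) p <- advect_nodes(p, matrix(c(0.25, 0, 0), 1), dt = 0.5)
  expect_equal(p[1, 1], 5 + 7 * 0.25 * 0.5)
})

test_that("particle placement is seeded, cleared from walls, non-overlapping", {
  vs <- straight_vessel(48, 22, grid = c(48, 24, 24))
  radii <- c(4, 2, 2)
  c1 <- place_particles(vs, radii, seed = 99)
  c2 <- place_particles(vs, radii, seed = 99)
  expect_identical(c1, c2)
  c3 <- place_particles(vs, radii, seed = 100)
  expect_false(identical(c1, c3))
  for (i in seq_along(radii)) {
    expect_lte(distance_d(c1[i, ], vs), 22 / 2 - radii[i] - 1)
  }
  dd <- as.matrix(dist(c1))
  expect_gte(dd[1, 2], radii[1] + radii[2] + 1)
  expect_gte(dd[1, 3], radii[1] + radii[3] + 1)
  expect_gte(dd[2, 3], radii[2] + radii[3] + 1)
  expect_error(place_particles(vs, rep(8, 10), seed = 1), "place")
})
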