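test_that("icosphere resolutions give closed meshes with Euler-consistent counts", {
  for (cfg in list(c(20, 12), c(80, 42), c(120, 62), c(320, 162),
                   c(480, 242))) {
    m <- icosphere(1, cfg[1])
    expect_equal(nrow(m$faces), cfg[1])
    expect_equal(nrow(m$vertices), cfg[2])
    expect_equal(nrow(m$vertices), nrow(m$faces) / 2 + 2)
    # every edge shared by exactly two faces
    expect_equal(nrow(m$edges), 3 * nrow(m$faces) / 2)
  }
})

test_that("icosphere converges to the sphere in area and volume", {
  # an inscribed triangulation always under-estimates the sphere; the
  # deficit scales as 1/Nf (about 5% at 120 faces, 1.4% at 480)
  m120 <- icosphere(2.5, 120)
  expect_equal(mesh_area(m120), 4 * pi * 2.5^2, tolerance = 0.06)
  m480 <- icosphere(2.5, 480)
  expect_equal(mesh_area(m480), 4 * pi * 2.5^2, tolerance = 0.02)
  expect_equal(mesh_volume(m480), 4 / 3 * pi * 2.5^3, tolerance = 0.03)
  expect_lt(abs(mesh_area(m480) / (4 * pi * 2.5^2) - 1),
            abs(mesh_area(m120) / (4 * pi * 2.5^2) - 1))
  m <- icosphere(3, 480, center = c(5, 6, 7))
  expect_equal(mesh_centroid(m), c(5, 6, 7), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("biconcave projection produces the discocyte", {
  R <- 3.5
  m <- biconcave_mesh(R, 480)
  expect_equal(nrow(m$faces), 480)
  expect_equal(nrow(m$vertices), 242)
  r <- sqrt(m$vertices[, 1]^2 + m$vertices[, 3]^2)
  # rim collapses to the mid-plane, max radius is the requested scale
  expect_equal(max(r), R, tolerance = 1e-12)
  expect_lt(max(abs(m$vertices[abs(r - R) < 1e-9, 2])), 1e-12)
  # dimple: thinner at the axis than at mid-radius
  near_axis <- abs(m$vertices[r < 0.25 * R, 2])
  mid <- abs(m$vertices[abs(r - 0.65 * R) < 0.15 * R, 2])
  expect_lt(max(near_axis), min(0.45 * R, mean(mid) * 2))
  expect_gt(mean(mid), mean(near_axis))
  # mirror symmetry about the mid-plane
  key <- function(v) paste(round(v[, 1], 9), round(abs(v[, 2]), 9),
                           round(v[, 3], 9))
  expect_setequal(key(m$vertices), key(m$vertices * rep(c(1, -1, 1),
                                                        each = 242)))
  expect_gt(mesh_volume(m), 0)
})

test_that("tri_mesh validates closure, orientation and manifoldness", {
  m <- icosphere(1, 20)
  # flipped orientation -> negative volume
  expect_error(tri_mesh(m$vertices, m$faces[, c(1, 3, 2)]), "outward")
  # drop a face -> not closed
  expect_error(tri_mesh(m$vertices, m$faces[-1, ]), "N = Nf/2 \\+ 2|closed")
  # open patches are allowed when requested
  patch <- flat_hinge()
  expect_equal(nrow(patch$edges), 1)
})

test_that("mesh OFF round trip preserves geometry", {
  m <- icosphere(1.5, 80, center = c(2, 3, 4))
  path <- withr::local_tempfile(fileext = ".off")
  write_mesh_off(m, path)
  m2 <- read_mesh_off(path)
  expect_equal(m2$vertices, m$vertices, ignore_attr = TRUE)
  expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
})
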