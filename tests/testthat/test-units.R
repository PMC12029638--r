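test_that("lattice viscosity follows (mu/rho) dt/dx^2", {
  us <- unit_system(dx = 1e-6, dt = 1.8e-8, rho = 1050, mu = 1.2e-3)
  expect_equal(lattice_viscosity(us), 0.0205714, tolerance = 1e-5)
  expect_equal(lattice_viscosity(unit_system(1, 1, 1, 1 / 6)), 1 / 6)
  # linear in dt
  us2 <- unit_system(dx = 1e-6, dt = 3.6e-8, rho = 1050, mu = 1.2e-3)
  expect_equal(lattice_viscosity(us2), 2 * lattice_viscosity(us))
  expect_error(unit_system(dx = -1), "positive")
})

test_that("relaxation time maps viscosity through tau = 3 nu + 1/2", {
  rt <- relaxation_from_viscosity(0.0205714)
  expect_equal(rt$tau, 0.561714, tolerance = 1e-5)
  expect_equal(signif(rt$omega, 3), 1.78)
  expect_equal(relaxation_from_viscosity(1 / 6),
               list(tau = 1, omega = 1))
  # nu -> 0+ limit: tau -> 1/2, omega -> 2
  rt0 <- relaxation_from_viscosity(1e-12)
  expect_lt(abs(rt0$tau - 0.5), 1e-11)
  expect_lt(abs(rt0$omega - 2), 1e-10)
  expect_error(relaxation_from_viscosity(0), "positive")
  # inverse identity on tau in (0.5, 3)
  for (tau in c(0.51, 0.8, 1, 1.7, 2.9)) {
    expect_equal(relaxation_from_viscosity(viscosity_from_relaxation(tau))$tau,
                 tau)
  }
})

test_that("velocity conversion round-trips and matches the flow-rate bridge", {
  us <- unit_system()
  expect_equal(to_physical_velocity(0.0012, us), 0.0667, tolerance = 1e-3)
  expect_equal(to_physical_velocity(0, us), 0)
  expect_equal(to_physical_velocity(1, unit_system(dt = 1e-6)), 1)
  u <- c(0, 1e-4, 0.01, 0.3)
  expect_equal(to_physical_velocity(to_lattice_velocity(u, us), us), u)
})

test_that("Poiseuille driving acceleration follows 32 nu^2 Re / D^3", {
  expect_equal(poiseuille_acceleration(1000, 1e-6, 50e-6), 2.56e5)
  expect_equal(poiseuille_acceleration(0, 1e-6, 50e-6), 0)
  expect_equal(poiseuille_acceleration(500, 1e-6, 50e-6),
               poiseuille_acceleration(1000, 1e-6, 50e-6) / 2)
  # consistency: Um and Re recover the target
  a <- poiseuille_acceleration(5, 1 / 6, 22)
  expect_equal(reynolds_number(mean_velocity(a, 22, 1 / 6), 22, 1 / 6), 5)
})

test_that("physical parameter table converts consistently to lattice units", {
  # the lattice column of the reference parameter set was produced with the
  # 15 ns step; the area-dilation row and carrier-radius row are
  # typographically inconsistent in the source and are excluded (physical
  # values are authoritative everywhere in the package)
  us <- unit_system(dt = 1.5e-8)
  p <- rbc_parameters()
  expect_equal(to_lattice(attr(p, "radius"), us, "length"), 3.5)
  printed <- c(ks = 1.08e-6, kB = 4.32e-8, kA = 0.108, kV = 0.216)
  got <- c(ks = to_lattice(p$ks, us, "surface_modulus"),
           kB = to_lattice(p$kB, us, "bending_modulus"),
           kA = to_lattice(p$kA, us, "surface_modulus"),
           kV = to_lattice(p$kV, us, "volume_modulus"))
  expect_true(all(abs(got - printed) / printed < 0.05))
  # drug-carrier stiffness sweep table is well-formed and monotone
  tab <- dc_stiffness_cases()
  expect_equal(nrow(tab), 5)
  expect_true(all(diff(tab$ks) > 0))
})

test_that("to_lattice and to_physical are mutually inverse", {
  us <- unit_system()
  for (w in c("length", "velocity", "acceleration", "force",
              "surface_modulus", "bending_modulus", "volume_modulus",
              "kinematic_viscosity", "shear_rate")) {
    expect_equal(to_physical(to_lattice(3.7, us, w), us, w), 3.7)
  }
})
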