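test_that("strain energy is zero at identity and matches hand evaluation", {
  mat <- wall_material()
  expect_identical(strain_energy(3, 1, mat), 0)
  lam <- 1.1
  I1 <- lam^2 + 2 / lam
  expect_equal(strain_energy(I1, 1, mat), 166e3 * (I1 - 3), tolerance = 1e-12)
  expect_equal(strain_energy(I1, 1, mat), 4678.2, tolerance = 1e-4)
  # incompressible material rejects J != 1
  expect_error(strain_energy(3.1, 1.05, mat), "J = 1")
  # compressible variant: volumetric term active
  matc <- wall_material(D1 = 1e-6)
  expect_equal(strain_energy(3, 1.01, matc), 1e6 * 1e-4, tolerance = 1e-10)
})

test_that("uniaxial nominal stress matches 2C1(lambda - lambda^-2)", {
  mat <- wall_material()
  expect_identical(uniaxial_nominal_stress(1, mat), 0)
  expect_equal(uniaxial_nominal_stress(1.1, mat), 90.82e3, tolerance = 1e-3)
  # strictly increasing
  lams <- seq(0.6, 2, by = 0.05)
  expect_true(all(diff(uniaxial_nominal_stress(lams, mat)) > 0))
  # small-strain slope is the incompressible Young's modulus 6 C1
  h <- 1e-7
  slope <- (uniaxial_nominal_stress(1 + h, mat) -
              uniaxial_nominal_stress(1 - h, mat)) / (2 * h)
  expect_equal(slope, 6 * mat$C1, tolerance = 1e-6)
})

test_that("uniaxial stress is the stretch-derivative of the isochoric energy", {
  mat <- wall_material()
  W_of <- function(l) strain_energy(l^2 + 2 / l, 1, mat)
  h <- 1e-6
  for (lam in c(0.8, 1.05, 1.3, 1.8)) {
    dW <- (W_of(lam + h) - W_of(lam - h)) / (2 * h)
    expect_equal(dW, uniaxial_nominal_stress(lam, mat), tolerance = 1e-5)
  }
})

test_that("tube equilibrium solves the prestressed Laplace balance", {
  mat <- wall_material()
  st0 <- tube_equilibrium(0, 1.6e-3, 125e-6, mat)
  expect_equal(st0$stretch, 1)
  expect_equal(st0$displacement, 0)
  st <- tube_equilibrium(2000, 1.6e-3, 125e-6, mat)
  expect_equal(st$stretch, 1.020, tolerance = 1e-3)
  expect_equal(st$displacement, 0.033e-3, tolerance = 2e-2)
  # residual of the governing balance at the returned root
  mu <- 2 * mat$C1
  res <- mu * (st$stretch^2 - st$stretch^-2) -
    2000 * st$stretch^2 * 1.6e-3 / 125e-6
  expect_lt(abs(res) / (mu * st$stretch^2), 1e-10)
  # lambda(P) strictly increasing on its domain
  Ps <- seq(0, 20e3, length.out = 25)
  ls <- vapply(Ps, function(P) tube_equilibrium(P, 1.6e-3, 125e-6, mat)$stretch, 0)
  expect_true(all(diff(ls) > 0))
  expect_error(tube_equilibrium(2 * mat$C1 * 125e-6 / 1.6e-3 + 1, 1.6e-3,
                                125e-6, mat), "stability")
})

test_that("sphere equilibrium has the balloon limit point at 7^(1/6)", {
  mat <- wall_material()
  expect_equal(sphere_equilibrium(0, 2.5e-3, 27e-6, mat)$stretch, 1)
  # independent numeric maximization of P(lambda) as the oracle
  mu <- 2 * mat$C1
  p_of <- function(l) 2 * mu * (27e-6 / 2.5e-3) * (l^-1 - l^-7)
  opt <- optimize(p_of, c(1, 3), maximum = TRUE, tol = 1e-12)
  expect_equal(opt$maximum, 7^(1 / 6), tolerance = 1e-6)
  st <- sphere_equilibrium(1000, 2.5e-3, 27e-6, mat)
  expect_lt(abs(st$residual), 1e-8)
  expect_equal(st$P_max, opt$objective, tolerance = 1e-10)
  expect_equal(st$P_max, 4.44e3, tolerance = 2e-3)
  expect_error(sphere_equilibrium(5000, 2.5e-3, 27e-6, mat), "limit point")
})

test_that("membrane wall update reproduces the tube oracle under uniform load", {
  ch <- channel_fixture()
  mat <- wall_material()
  ic <- wall_interface(ch, mat, prestress_pressure = 0)
  # zero traction -> zero displacement
  up0 <- membrane_wall_update(ic, matrix(0, nrow(ic$nodes), 2), mat)
  expect_identical(max(abs(up0$displacement)), 0)
  # uniform outward pressure: mid-span displacement equals the tube response
  P <- 2000
  up <- membrane_wall_update(ic, ic$normals * P, mat)
  st <- tube_equilibrium(P, 1.6e-3, 125e-6, mat)
  mid <- which.min((ic$nodes[, 1] - 6e-3)^2 + (ic$nodes[, 2] - 1.6e-3)^2)
  expect_equal(up$normal_displacement[mid], st$displacement, tolerance = 2e-2)
  # clamped anchors stay put
  expect_true(all(abs(up$displacement[ic$anchors, ]) == 0))
  # displacement field is continuous (no jumps beyond load scale)
  expect_lt(max(abs(diff(up$normal_displacement[order(ic$nodes[, 1])]))),
            st$displacement)
})

test_that("the pure string limit matches the analytic extensible-arc solution", {
  # with the hoop foundation switched off (infinite local radius) the wall
  # is an extensible string; under uniform normal pressure its equilibrium
  # is a circular arc with constant tension T = q R, which gives a scalar
  # equation for the arc radius — an independent closed-form oracle
  ch <- channel_fixture()
  mat <- wall_material()
  ic <- wall_interface(ch, mat, prestress_pressure = 0)
  ic$local_radius[] <- Inf
  ic$pre_tension[] <- 1e-3            # break the flat-state singularity
  q <- 50                              # Pa
  L <- 12e-3
  t0 <- mat$thickness_artery
  muw <- 2 * mat$C1
  arc_eq <- function(R) {
    lam <- (2 * R * asin(L / (2 * R))) / L
    t0 * muw * (lam - lam^-3) - q * R
  }
  R <- uniroot(arc_eq, c(L / 2 + 1e-6, 100), tol = 1e-14)$root
  sag <- R - sqrt(R^2 - L^2 / 4)
  up <- membrane_wall_update(ic, ic$normals * q, mat)
  mid <- which.min((ic$nodes[, 1] - 6e-3)^2 + (ic$nodes[, 2] - 1.6e-3)^2)
  expect_equal(up$normal_displacement[mid], sag, tolerance = 1e-2)
})

test_that("membrane stiffness scales as expected", {
  ch <- channel_fixture()
  # doubling C1 halves small-load displacement to first order
  m1 <- wall_material(C1 = 166e3)
  m2 <- wall_material(C1 = 332e3)
  ic1 <- wall_interface(ch, m1, prestress_pressure = 0)
  ic2 <- wall_interface(ch, m2, prestress_pressure = 0)
  d1 <- max(abs(membrane_wall_update(ic1, ic1$normals * 100, m1)$normal_displacement))
  d2 <- max(abs(membrane_wall_update(ic2, ic2$normals * 100, m2)$normal_displacement))
  expect_equal(d2 / d1, 0.5, tolerance = 2e-2)
  # rigid limit: C1 = 1e12 Pa -> displacements below 1e-9 m
  mr <- wall_material(C1 = 1e12)
  icr <- wall_interface(ch, mr, prestress_pressure = 16000)
  dr <- membrane_wall_update(icr, icr$normals * 500, mr)
  expect_lt(max(abs(dr$displacement)), 1e-9)
})
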