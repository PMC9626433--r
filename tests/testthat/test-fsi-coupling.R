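test_that("interface traction reduces to -p n for a hydrostatic state", {
  ch <- channel_fixture()
  n <- nrow(ch$nodes)
  ff <- manual_field(ch, matrix(0, n, 2), pressure = 1234)
  tr <- interface_traction(ff, ch, newtonian_blood())
  expect_equal(tr$traction, -1234 * tr$normal, tolerance = 1e-12)
  expect_equal(tr$normal_component, rep(-1234, length(tr$node)), tolerance = 1e-12)
  expect_lt(max(abs(tr$tangential)), 1e-9)
})

test_that("interface traction on Poiseuille flow carries G h/2 shear and -p normal", {
  ch <- channel_fixture()
  pf <- poiseuille_field(ch)
  tr <- interface_traction(pf, ch, newtonian_blood())
  G <- 12 * 0.004 * 0.23 / (3.2e-3)^2
  xs <- ch$nodes[tr$node, 1]
  inner <- xs > 2e-3 & xs < 10e-3
  tmag <- sqrt(rowSums(tr$tangential^2))
  expect_equal(max(abs(tmag[inner] - G * 3.2e-3 / 2)), 0, tolerance = 1e-6)
  expect_equal(tr$normal_component[inner], -pf$pressure_abs[tr$node][inner],
               tolerance = 1e-9)
})

test_that("interface traction transforms as a vector under rotation", {
  ch <- build_channel(length = 6e-3, width = 3.2e-3, mesh_size = 4e-4)
  pf <- poiseuille_field(ch)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  chr <- rotate_mesh(ch, th)
  pfr <- pf
  pfr$velocity <- pf$velocity %*% t(R)
  tr0 <- interface_traction(pf, ch, newtonian_blood())
  trr <- interface_traction(pfr, chr, newtonian_blood())
  expect_equal(trr$traction, tr0$traction %*% t(R), tolerance = 1e-8)
})

test_that("Aitken factor follows the classical update with clamping", {
  # zero current residual: converged, factor untouched
  expect_equal(aitken_factor(list(c(1, 1), c(0, 0)), omega = 0.37), 0.37)
  # identical consecutive residuals: degenerate -> halve towards stability
  expect_equal(aitken_factor(list(c(1, 2), c(1, 2)), omega = 0.8), 0.4)
  # hand-evaluated update: r1 = (1,0), r2 = (0.5,0)
  # omega' = -omega * <r1, r2-r1> / |r2-r1|^2 = -0.5 * (-0.5)/0.25 = 1
  expect_equal(aitken_factor(list(c(1, 0), c(0.5, 0)), omega = 0.5), 1.0)
  # clamp respected on adversarial histories
  expect_equal(aitken_factor(list(c(1, 0), c(100, 0)), omega = 0.9), 0.1)
  expect_equal(aitken_factor(list(c(1, 0), c(0.9, 0)), omega = 0.9), 1.0)
  # short history: initial factor returned
  expect_equal(aitken_factor(list(c(1, 0)), omega = 0.5), 0.5)
})

test_that("mesh morphing preserves structure and handles rigid motion", {
  ch <- channel_fixture()
  n <- nrow(ch$nodes)
  # zero displacement -> identical mesh object geometry
  m0 <- morph_mesh(ch, matrix(0, n, 2))
  expect_identical(m0$nodes, ch$nodes)
  # rigid translation of the whole boundary translates all nodes exactly
  d <- matrix(rep(c(5e-5, -3e-5), each = n), n, 2)
  mt <- morph_mesh(ch, d)
  expect_equal(mt$nodes, ch$nodes + d[1, ][col(ch$nodes)], tolerance = 1e-12)
  # a smooth bulge keeps triangle quality within 50% of the original
  ic <- wall_interface(ch, wall_material(), 0)
  bump <- 2e-4 * exp(-((ic$nodes[, 1] - 6e-3) / 2e-3)^2)
  dm <- matrix(0, n, 2)
  dm[ic$ids, ] <- ic$normals * bump
  mb <- morph_mesh(ch, dm)
  q0 <- min(cerebrofsi:::tri_areas(ch$nodes, ch$tri))
  qb <- min(cerebrofsi:::tri_areas(mb$nodes, mb$tri))
  expect_gte(qb, 0.5 * q0)
  expect_true(isTRUE(cerebrofsi:::validate_mesh(mb)))
  # excessive displacement is rejected
  expect_error(morph_mesh(ch, dm * 20), "exceeds")
})

test_that("one outer iteration with unit relaxation is the one-way coupling", {
  ch <- channel_fixture()
  p <- rheology_params(); mat <- wall_material(); bc <- flow_bcs()
  # manual naive sequential coupling
  f0 <- solve_steady_flow(ch, p, bc)
  tr <- interface_traction(f0, ch, p)
  ic <- wall_interface(ch, mat, bc$inlet_reference_pressure)
  dt <- tr$traction + bc$outlet_pressure * ic$normals
  up <- membrane_wall_update(ic, dt, mat)
  # solve_fsi with a loose tolerance stops after that exact first iteration
  res <- solve_fsi(ch, p, mat, bc,
                   coupling_settings(relaxation = "fixed", initial_factor = 1,
                                     interface_tol = 1))
  expect_identical(res$state$iterations, 1L)
  expect_equal(res$displacement[ic$ids, ], up$displacement, tolerance = 1e-12)
})

test_that("coupled channel FSI converges with Aitken-stabilized increments", {
  ch <- channel_fixture()
  res <- solve_fsi(ch, rheology_params(), wall_material(), flow_bcs(),
                   coupling_settings())
  expect_true(res$state$converged)
  inc <- res$state$increments
  expect_lt(inc[length(inc)], coupling_settings()$interface_tol)
  if (length(inc) > 3)
    expect_true(all(diff(inc[-(1:2)]) <= 1e-12))
  # no-slip on the deformed configuration: wall velocities are zero
  expect_true(all(res$flow$velocity[res$mesh$wall_nodes, ] == 0))
  # membrane residual below its solver tolerance at convergence
  expect_lt(res$state$membrane_residual, 1e-4)
})

test_that("the rigid limit recovers the rigid-wall flow", {
  ch <- channel_fixture()
  res <- solve_fsi(ch, rheology_params(), wall_material(C1 = 1e12), flow_bcs(),
                   coupling_settings())
  expect_lt(max(sqrt(rowSums(res$displacement^2))), 1e-9)
  ref <- channel_hb_flow()
  expect_lt(max(abs(res$flow$velocity - ref$velocity)), 1e-8)
})
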