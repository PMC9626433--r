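test_that("parabolic inlet profile has the right peak, flux and zeros", {
  ch <- channel_fixture()
  inl <- inlet_profile(0.23, ch)
  expect_equal(inl$profile(0), 1.5 * 0.23, tolerance = 1e-12)
  expect_lte(max(inl$velocity[, 1]), 1.5 * 0.23)
  expect_true(all(abs(inl$velocity[, 2]) == 0))
  # profile integral / width = mean (quadrature identity)
  igr <- integrate(inl$profile, -1.6e-3, 1.6e-3, rel.tol = 1e-12)
  expect_equal(igr$value / 3.2e-3, 0.23, tolerance = 1e-12)
  # flux of the continuous profile = mean * width
  expect_equal(igr$value, 0.23 * 3.2e-3, tolerance = 1e-12)
  # zero mean -> zero field
  expect_true(all(inlet_profile(0, ch)$velocity == 0))
})

test_that("Newtonian channel solve matches plane Poiseuille", {
  ch <- channel_fixture()
  ff <- channel_newtonian_flow()
  expect_true(ff$converged)
  G <- 12 * 0.004 * 0.23 / (3.2e-3)^2
  uex <- channel_flow_oracle(G, 3.2e-3, newtonian_blood())$profile(ch$nodes[, 2])
  l2 <- sqrt(sum((ff$velocity[, 1] - uex)^2) / sum(uex^2))
  expect_lt(l2, 0.01)
  # WSS within 2% of the oracle wall value G h / 2
  w <- compute_wss(ff, ch, newtonian_blood())
  xs <- ch$nodes[w$node, 1]
  inner <- xs > 2e-3 & xs < 10e-3
  expect_lt(max(abs(w$wss_mag[inner] / (G * 3.2e-3 / 2) - 1)), 0.02)
})

test_that("Herschel-Bulkley channel WSS matches the oracle at matched flux", {
  ch <- long_channel_fixture()
  ff <- long_channel_hb_flow()
  p <- rheology_params()
  vmean <- abs(port_flux(ch, ff, "INLET")) / 3.2e-3
  G <- cerebrofsi:::channel_gradient_for_mean(vmean, 3.2e-3, p)
  tw <- channel_flow_oracle(G, 3.2e-3, p)$wall_shear_stress
  w <- compute_wss(ff, ch, p)
  xs <- ch$nodes[w$node, 1]
  inner <- xs > 25e-3 & xs < 38e-3     # fully developed stretch
  expect_lt(max(abs(w$wss_mag[inner] / tw - 1)), 0.03)
})

test_that("discrete mass is conserved at every converged state", {
  ch <- channel_fixture()
  ff <- channel_hb_flow()
  fin <- port_flux(ch, ff, "INLET")
  fout <- port_flux(ch, ff, "OUTLET_1")
  expect_lt(abs(fin + fout) / abs(fin), 1e-8)
  m <- intact_mesh()
  fi <- intact_flow()
  tot <- port_flux(m, fi, "INLET") + port_flux(m, fi, "OUTLET_1") +
    port_flux(m, fi, "OUTLET_2")
  expect_lt(abs(tot) / abs(port_flux(m, fi, "INLET")), 1e-8)
  # inlet flux equals mean velocity * width (parabolic profile)
  expect_equal(abs(port_flux(m, fi, "INLET")), 0.23 * 3.2e-3, tolerance = 1e-3)
})

test_that("velocity error converges with observed order of at least 1.5", {
  # the discretization is nodally exact for the parabolic (Newtonian)
  # profile, so the rate is measured on the non-polynomial Herschel-Bulkley
  # developed profile against the analytic oracle at matched flux
  p <- rheology_params()
  errs <- vapply(c(4e-4, 2e-4), function(hs) {
    ch <- if (hs == 2e-4) long_channel_fixture() else
      build_channel(length = 40e-3, width = 3.2e-3, mesh_size = hs)
    ff <- if (hs == 2e-4) long_channel_hb_flow() else
      solve_steady_flow(ch, p, flow_bcs())
    vmean <- abs(port_flux(ch, ff, "INLET")) / 3.2e-3
    G <- cerebrofsi:::channel_gradient_for_mean(vmean, 3.2e-3, p)
    uex <- channel_flow_oracle(G, 3.2e-3, p)$profile(ch$nodes[, 2])
    sel <- ch$nodes[, 1] > 25e-3 & ch$nodes[, 1] < 38e-3
    sqrt(sum((ff$velocity[sel, 1] - uex[sel])^2) / sum(uex[sel]^2))
  }, 0)
  order <- log2(errs[1] / errs[2])
  expect_gte(order, 1.5)
})

test_that("rotating the mesh and boundary conditions rotates the solution", {
  pn <- newtonian_blood()
  ch <- build_channel(length = 8e-3, width = 3.2e-3, mesh_size = 4e-4)
  f0 <- solve_steady_flow(ch, pn, flow_bcs())
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  chr <- rotate_mesh(ch, th)
  fr <- solve_steady_flow(chr, pn, flow_bcs())
  urot <- f0$velocity %*% t(R)
  scale <- max(abs(urot))
  expect_lt(max(abs(fr$velocity - urot)) / scale, 1e-8)
  expect_lt(max(abs(fr$pressure - f0$pressure)) / max(abs(f0$pressure)), 1e-8)
})

test_that("the stenosed solution approaches the intact one as degree -> 0", {
  m0 <- intact_mesh()
  f0 <- intact_flow()
  sp <- scenario_spec("ICAS", stenoses = list(
    stenosis_spec("PARENT", 4.8e-3, 1.6e-3, 1e-4, "WALL_A")))
  ms <- build_scenario(sp)
  fs <- solve_steady_flow(ms, rheology_params(), flow_bcs())
  rel <- sqrt(sum((fs$velocity - f0$velocity)^2) / sum(f0$velocity^2))
  expect_lt(rel, 1e-3)
})

test_that("the quasi-steady ramp starts at rest and ends at the steady solve", {
  ch <- channel_fixture()
  p <- rheology_params()
  st <- solver_settings(ramp_steps = 5)
  rs <- ramp_series(ch, p, flow_bcs(), st)
  expect_length(rs$fields, 6)
  expect_true(all(rs$fields[[1]]$velocity == 0))
  expect_true(!is.unsorted(rs$times, strictly = TRUE))
  # monotone inlet flux along the ramp
  flux <- vapply(rs$fields, function(f) abs(port_flux(ch, f, "INLET")), 0)
  expect_true(all(diff(flux) >= -1e-12))
  # final step equals the direct steady solve within solver tolerance
  ref <- channel_hb_flow()
  rel <- sqrt(sum((rs$fields[[6]]$velocity - ref$velocity)^2) /
                sum(ref$velocity^2))
  expect_lt(rel, 1e-5)
})

test_that("solver rejects and reports bad inputs", {
  ch <- channel_fixture()
  expect_error(flow_bcs(inlet_mean_velocity = -1), ">= 0")
  bad <- ch
  bad$tri[1, ] <- bad$tri[1, c(1, 3, 2)]
  expect_error(solve_steady_flow(bad, rheology_params(), flow_bcs()),
               "inverted")
})
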