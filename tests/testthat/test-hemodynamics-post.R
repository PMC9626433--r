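test_that("WSS vanishes for translation and rigid-rotation fields", {
  ch <- channel_fixture()
  n <- nrow(ch$nodes)
  # uniform translation: zero gradient
  ft <- manual_field(ch, cbind(rep(0.3, n), rep(-0.1, n)))
  wt <- compute_wss(ft, ch, newtonian_blood())
  expect_lt(max(wt$wss_mag), 1e-10)
  # rigid rotation about the channel center: antisymmetric gradient
  om <- 120
  c0 <- c(6e-3, 0)
  fr <- manual_field(ch, cbind(-om * (ch$nodes[, 2] - c0[2]),
                               om * (ch$nodes[, 1] - c0[1])))
  wr <- compute_wss(fr, ch, newtonian_blood())
  expect_lt(max(wr$wss_mag), 1e-6)
})

test_that("WSS on analytic Poiseuille equals 6 mu V / h and is tangential", {
  ch <- channel_fixture()
  pf <- poiseuille_field(ch)
  w <- compute_wss(pf, ch, newtonian_blood())
  xs <- ch$nodes[w$node, 1]
  inner <- xs > 2e-3 & xs < 10e-3
  expect_equal(w$wss_mag[inner],
               rep(6 * 0.004 * 0.23 / 3.2e-3, sum(inner)), tolerance = 1e-6)
  # tangentiality invariant: WSS vector is orthogonal to the wall normal
  dots <- abs(rowSums(w$wss_vector * w$normal))
  expect_lt(max(dots / pmax(w$wss_mag, 1e-12)), 1e-10)
})

test_that("Newtonian WSS statistics are homogeneous of degree one in velocity", {
  ch <- channel_fixture()
  pf1 <- poiseuille_field(ch, vmean = 0.23)
  pf2 <- poiseuille_field(ch, vmean = 0.46)
  w1 <- compute_wss(pf1, ch, newtonian_blood())
  w2 <- compute_wss(pf2, ch, newtonian_blood())
  s1 <- summarize_scenario(w1, pf1, ch)
  s2 <- summarize_scenario(w2, pf2, ch)
  expect_equal(s2$peak_wss / s1$peak_wss, 2, tolerance = 1e-9)
  expect_equal(s2$median_wss / s1$median_wss, 2, tolerance = 1e-9)
})

test_that("a constant-shear field gives equal max and weighted median WSS", {
  ch <- channel_fixture()
  gam <- 150
  fc <- manual_field(ch, cbind(gam * (ch$nodes[, 2] + 1.6e-3),
                               rep(0, nrow(ch$nodes))))
  w <- compute_wss(fc, ch, newtonian_blood())
  s <- summarize_scenario(w, fc, ch)
  expect_equal(s$peak_wss, 0.004 * gam, tolerance = 1e-9)
  expect_equal(s$median_wss, s$peak_wss, tolerance = 1e-9)
})

test_that("target-point series samples nodes exactly and checks inputs", {
  ch <- channel_fixture()
  pf <- poiseuille_field(ch)
  w <- compute_wss(pf, ch, newtonian_blood())
  ser <- extract_series(0, list(pf), ch, target = "mid_wall",
                        wss_fields = list(w))
  expect_identical(nrow(ser), 1L)
  tgt <- target_node(ch, "mid_wall")
  expect_identical(ser$velocity, sqrt(sum(pf$velocity[tgt, ]^2)))
  expect_identical(ser$pressure, pf$pressure_abs[tgt])
  # zero-flow state gives zeros
  z <- manual_field(ch, matrix(0, nrow(ch$nodes), 2))
  wz <- compute_wss(z, ch, newtonian_blood())
  serz <- extract_series(c(0, 1), list(z, z), ch, "mid_wall",
                         wss_fields = list(wz, wz))
  expect_true(all(serz$velocity == 0) && all(serz$wss < 1e-12))
  expect_error(extract_series(c(1, 0), list(pf, pf), ch, "mid_wall"),
               "increasing")
  expect_error(extract_series(0, list(pf), ch, "no_such_target"),
               "not defined")
})

test_that("summary statistics of the intact scenario sit in physiological bands", {
  m <- intact_mesh()
  w <- intact_wss()
  s <- summarize_scenario(w, intact_flow(), m)
  expect_identical(s$scenario, "INTACT")
  expect_gt(s$median_wss, 1)
  expect_lt(s$median_wss, 7)
  expect_gt(s$peak_velocity, 0.3)      # >= parabola peak of the daughters
  expect_lt(s$peak_velocity, 0.6)
  # apex is a stagnation region: far below the wall-wide peak
  expect_lt(s$target_wss[["apex"]], s$peak_wss / 2)
})

test_that("VTK and sidecar serialization round out the mesh artifacts", {
  m <- intact_mesh()
  f1 <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f1, point_data = list(
    pressure = intact_flow()$pressure, velocity = intact_flow()$velocity))
  txt <- readLines(f1)
  expect_identical(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", txt)))
  expect_true(any(grepl("^CELLS", txt)))
  # 0-based connectivity: minimum index must be 0
  cells <- txt[(grep("^CELLS", txt) + 1):(grep("^CELL_TYPES", txt) - 1)]
  idx <- as.integer(unlist(strsplit(cells, " "))[-1])
  expect_identical(min(as.integer(vapply(strsplit(cells, " "),
                                         function(x) x[2], ""))), 0L)
  f2 <- tempfile(fileext = ".json")
  write_mesh_sidecar(m, f2)
  side <- jsonlite::read_json(f2)
  expect_identical(side$scenario, "INTACT")
  expect_identical(side$n_nodes, nrow(m$nodes))
  expect_identical(side$target_points$apex, m$target[["apex"]] - 1L)
  unlink(c(f1, f2))
})
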