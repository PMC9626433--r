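mesh_ok <- function(mesh) isTRUE(cerebrofsi:::validate_mesh(mesh))

test_that("all three scenario meshes satisfy the structural invariants", {
  for (sc in c("INTACT", "ICAS", "ACA")) {
    m <- if (sc == "INTACT") intact_mesh() else build_scenario(scenario_spec(sc))
    expect_true(mesh_ok(m), label = sc)
    expect_true(all(cerebrofsi:::tri_areas(m$nodes, m$tri) > 0), label = sc)
    # boundary edge count partitions exactly into the four tags
    expect_identical(sum(table(m$boundary_tag)), nrow(m$boundary_edges))
    expect_setequal(unique(m$boundary_tag),
                    c("INLET", "OUTLET_1", "OUTLET_2", "WALL"))
    # channel widths at the ports equal the spec diameters
    for (tg in c("INLET", "OUTLET_1", "OUTLET_2")) {
      ids <- unique(as.integer(m$boundary_edges[m$boundary_tag == tg, ]))
      span <- sqrt(sum((apply(m$nodes[ids, ], 2, max) -
                          apply(m$nodes[ids, ], 2, min))^2))
      want <- if (tg == "INLET") 3.2e-3 else 2.0e-3
      expect_equal(span, want, tolerance = 1e-9)
    }
  }
})

test_that("stenosis throat realizes the full occlusion degree", {
  m <- build_scenario(scenario_spec("ICAS"))
  # parent throat: narrowest cross-width near the bump center (x = -4.8 mm)
  xs <- round(m$nodes[, 1], 12)
  stations <- sort(unique(xs[xs > -5.6e-3 & xs < -4.0e-3]))
  widths <- vapply(stations, function(x) {
    sel <- xs == x
    diff(range(m$nodes[sel, 2]))
  }, 0)
  expect_equal(min(widths), (1 - 0.5) * 3.2e-3, tolerance = 1e-2)
  # daughter-1 throat: cross-channel extent in the centerline frame at the
  # bump center (3 mm downstream of the apex)
  g <- m$geom
  pts <- m$nodes[m$nodes[, 2] > 0, ]
  s_cl <- (pts[, 1] - g$J[1]) * g$u1[1] + (pts[, 2] - g$J[2]) * g$u1[2] -
    g$s_apex_on_cl
  t_cl <- -(pts[, 1] - g$J[1]) * g$u1[2] + (pts[, 2] - g$J[2]) * g$u1[1]
  win <- abs(s_cl - 3e-3) < 0.06e-3
  expect_true(any(win))
  expect_equal(diff(range(t_cl[win])), (1 - 0.5) * 2.0e-3, tolerance = 3e-2)
})

test_that("stenosis profile is a C1 cosine bump with the printed quadrature", {
  st <- stenosis_spec("PARENT", 4.8e-3, 1.6e-3, 0.5)
  w <- 3.2e-3
  # maximum inset at the center is degree * w / 2
  expect_equal(stenosis_profile(4.8e-3, st, w), 0.5 * w / 2)
  # zero value and zero slope at the bump ends
  expect_equal(stenosis_profile(4.8e-3 + 0.8e-3, st, w), 0)
  eps <- 1e-7
  slope <- (stenosis_profile(4.8e-3 + 0.8e-3, st, w) -
              stenosis_profile(4.8e-3 + 0.8e-3 - eps, st, w)) / eps
  expect_lt(abs(slope), 1e-3)
  expect_identical(stenosis_profile(1e-3, st, w), 0)
  # integral over the bump equals degree * w * L / 4
  igr <- integrate(function(s) stenosis_profile(s, st, w), 4.0e-3, 5.6e-3,
                   rel.tol = 1e-10)
  expect_equal(igr$value, 0.5 * w * 1.6e-3 / 4, tolerance = 1e-8)
})

test_that("a vanishing stenosis degree reproduces the intact mesh node-for-node", {
  spe <- scenario_spec("ICAS", stenoses = list(
    stenosis_spec("PARENT", 4.8e-3, 1.6e-3, 1e-9, "WALL_A")))
  me <- build_scenario(spe)
  mi <- intact_mesh()
  expect_identical(nrow(me$nodes), nrow(mi$nodes))
  expect_identical(me$tri, mi$tri)
  expect_lt(max(abs(me$nodes - mi$nodes)), 1e-11)
})

test_that("symmetric specs give mirror-symmetric geometry", {
  sp <- scenario_spec("ICAS", stenoses = list(
    stenosis_spec("DAUGHTER_1", 3e-3, 1.6e-3, 0.5, "WALL_A"),
    stenosis_spec("DAUGHTER_2", 3e-3, 1.6e-3, 0.5, "WALL_A")))
  m <- build_scenario(sp)
  mirrored <- cbind(m$nodes[, 1], -m$nodes[, 2])
  # every mirrored node must coincide with some node to within 1e-12 m
  key <- paste(round(m$nodes[, 1] * 1e12), round(m$nodes[, 2] * 1e12))
  keym <- paste(round(mirrored[, 1] * 1e12), round(mirrored[, 2] * 1e12))
  expect_true(all(keym %in% key))
})

test_that("mesh construction is deterministic (byte-identical files)", {
  f1 <- tempfile(fileext = ".vtk"); f2 <- tempfile(fileext = ".vtk")
  write_mesh_vtk(build_scenario(scenario_spec("ACA")), f1)
  write_mesh_vtk(build_scenario(scenario_spec("ACA")), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("target points sit at the analytic locations and survive refinement", {
  mi <- intact_mesh()
  tp <- target_points(mi)
  expect_named(tp, "apex")
  expect_lt(sqrt(sum(mi$nodes[tp["apex"], ]^2)), mi$spec$mesh_size)
  ma <- build_scenario(scenario_spec("ACA"))
  tpa <- target_points(ma)
  expect_true(all(c("apex", "sac_vertex") %in% names(tpa)))
  vx <- ma$nodes[tpa["sac_vertex"], ]
  # vertex ~ neck offset + 2 * sac radius from the apex along the sac axis
  expect_equal(vx[1], ma$geom$sac_center[1] + ma$spec$sac_radius,
               tolerance = ma$spec$mesh_size / vx[1])
  expect_lt(abs(vx[2]), ma$spec$mesh_size)
  expect_error(target_node(mi, "sac_vertex"), "not defined")
  # refinement: snapped target moves by less than the coarse spacing
  mf <- refine(ma, 1.6)
  vx2 <- mf$nodes[target_points(mf)["sac_vertex"], ]
  expect_lt(sqrt(sum((vx - vx2)^2)), ma$spec$mesh_size)
})

test_that("refine rebuilds with a finer size field", {
  mi <- intact_mesh()
  expect_error(refine(mi, 0), "factor")
  same <- refine(mi, 1)
  expect_identical(nrow(same$nodes), nrow(mi$nodes))
  fine <- refine(mi, 2)
  expect_gte(nrow(fine$tri), 3 * nrow(mi$tri))
  # refined boundary stays within the coarse spacing of the coarse boundary
  cb <- unique(as.integer(mi$boundary_edges))
  fb <- unique(as.integer(fine$boundary_edges))
  dmax <- max(apply(fine$nodes[fb, ], 1, function(p)
    min(sqrt((mi$nodes[cb, 1] - p[1])^2 + (mi$nodes[cb, 2] - p[2])^2))))
  expect_lt(dmax, mi$spec$mesh_size)
})

test_that("ACA wall thickness map blends from artery to sac across the neck", {
  ma <- build_scenario(scenario_spec("ACA"))
  thk <- ma$wall_thickness[ma$wall_nodes]
  kinds <- ma$wall_kind[ma$wall_nodes]
  expect_true(all(thk[kinds == 1L] == 125e-6))
  sac_thk <- thk[kinds == 2L]
  expect_equal(min(sac_thk), 27e-6)           # deep sac reaches sac thickness
  expect_true(all(sac_thk >= 27e-6 - 1e-12 & sac_thk <= 125e-6 + 1e-12))
  # intermediate (blend band) values exist
  expect_true(any(sac_thk > 27e-6 & sac_thk < 125e-6))
})

test_that("invalid specs are rejected with descriptive errors", {
  expect_error(scenario_spec("INTACT", stenoses = default_stenoses()),
               "must not carry")
  expect_error(scenario_spec("ICAS", stenoses = list()), "at least one")
  expect_error(stenosis_spec("PARENT", 4.8e-3, 1.6e-3, 1.2), "degree")
  expect_error(build_scenario(scenario_spec("ICAS", stenoses = list(
    stenosis_spec("PARENT", 0.4e-3, 1.6e-3, 0.5)))), "inside its branch")
  expect_error(build_scenario(scenario_spec("ACA", sac_neck_width = 6e-3)),
               "self-intersecting")
})
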