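#' Stenosis description
#'
#' One atherosclerotic plaque, modelled as a C1-continuous cosine bump on one
#' wall of a branch. `degree` is the fraction of the local channel width
#' occluded at the throat, so a degree-0.5 plaque halves the lumen.
#'
#' @param branch One of `"PARENT"`, `"DAUGHTER_1"`, `"DAUGHTER_2"`.
#' @param center_offset Distance of the bump center from the bifurcation apex
#'   along the branch centerline, m.
#' @param length Bump length along the wall, m.
#' @param degree Fraction of the local channel width occluded (0 < degree < 1).
#' @param side `"WALL_A"` (outer wall) or `"WALL_B"` (inner wall).
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(branch = c("PARENT", "DAUGHTER_1", "DAUGHTER_2"),
                          center_offset, length, degree, side = "WALL_A") {
  branch <- match.arg(branch)
  side <- match.arg(side, c("WALL_A", "WALL_B"))
  if (!(degree > 0 && degree < 1)) stop("degree must be in (0, 1)")
  if (length <= 0) stop("stenosis length must be > 0")
  if (center_offset <= 0) stop("center_offset must be > 0")
  structure(list(branch = branch, center_offset = center_offset,
                 length = length, degree = degree, side = side),
            class = "stenosis_spec")
}

default_stenoses <- function() {
  list(stenosis_spec("PARENT",     4.8e-3, 1.6e-3, 0.5, "WALL_A"),
       stenosis_spec("DAUGHTER_1", 3.0e-3, 1.6e-3, 0.5, "WALL_A"),
       stenosis_spec("DAUGHTER_2", 3.0e-3, 1.6e-3, 0.5, "WALL_A"))
}

#' Scenario description for the parametric bifurcation geometries
#'
#' Defines one of the three study geometries on a planar (midplane) section:
#' `INTACT` — healthy bifurcation, parent diameter 3.2 mm branching into two
#' 2 mm daughters; `ICAS` — the same artery occluded by atherosclerotic
#' stenoses (three by default); `ACA` — the same bifurcation carrying a
#' saccular aneurysm of 2.5 mm radius at the apex (with the same plaques,
#' i.e. an atherosclerotic aneurysm). All lengths in meters, angles in
#' degrees. The bifurcation half-angle, stenosis placement and sac neck width
#' are not dictated by the study conditions and carry documented defaults.
#'
#' @param scenario `"INTACT"`, `"ICAS"` or `"ACA"`.
#' @param parent_diameter Parent artery diameter, m.
#' @param daughter_diameter Daughter branch diameter, m.
#' @param bifurcation_half_angle Half-angle between a daughter centerline and
#'   the parent axis, degrees.
#' @param parent_length,daughter_length Branch lengths, m.
#' @param stenoses List of [stenosis_spec()] objects (ICAS/ACA only).
#' @param sac_radius Aneurysm sac radius, m (ACA only).
#' @param sac_neck_width Width of the sac neck opening at the apex, m.
#' @param mesh_size Target element size, m.
#' @param seed Integer recorded with the mesh (the construction is fully
#'   deterministic; the seed is part of the reproducibility contract).
#' @return An object of class `scenario_spec`.
#' @examples
#' spec <- scenario_spec("INTACT")
#' mesh <- build_scenario(spec)
#' @export
scenario_spec <- function(scenario = c("INTACT", "ICAS", "ACA"),
                          parent_diameter = 3.2e-3,
                          daughter_diameter = 2.0e-3,
                          bifurcation_half_angle = 50,
                          parent_length = 12e-3,
                          daughter_length = 10e-3,
                          stenoses = NULL,
                          sac_radius = 2.5e-3,
                          sac_neck_width = 2.2e-3,
                          mesh_size = 2.5e-4,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  if (parent_diameter <= 0 || daughter_diameter <= 0) stop("diameters must be > 0")
  if (mesh_size <= 0) stop("mesh_size must be > 0")
  if (is.null(stenoses))
    stenoses <- if (scenario %in% c("ICAS", "ACA")) default_stenoses() else list()
  if (scenario == "INTACT" && length(stenoses) > 0)
    stop("INTACT scenario must not carry stenoses")
  if (scenario == "ICAS" && length(stenoses) < 1)
    stop("ICAS scenario requires at least one stenosis")
  if (scenario == "ACA" && !(sac_radius > 0))
    stop("ACA scenario requires sac_radius > 0")
  structure(list(scenario = scenario,
                 parent_diameter = parent_diameter,
                 daughter_diameter = daughter_diameter,
                 bifurcation_half_angle = bifurcation_half_angle,
                 parent_length = parent_length,
                 daughter_length = daughter_length,
                 stenoses = stenoses,
                 sac_radius = if (scenario == "ACA") sac_radius else 0,
                 sac_neck_width = sac_neck_width,
                 mesh_size = mesh_size,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s: parent %g mm, daughters %g mm, half-angle %g deg\n",
              x$scenario, x$parent_diameter * 1e3, x$daughter_diameter * 1e3,
              x$bifurcation_half_angle))
  if (length(x$stenoses))
    cat(sprintf("  %d stenoses (degrees: %s)\n", length(x$stenoses),
                paste(vapply(x$stenoses, `[[`, 0, "degree"), collapse = ", ")))
  if (x$sac_radius > 0)
    cat(sprintf("  saccular aneurysm: radius %g mm, neck %g mm\n",
                x$sac_radius * 1e3, x$sac_neck_width * 1e3))
  cat(sprintf("  mesh size %g mm, seed %d\n", x$mesh_size * 1e3, x$seed))
  invisible(x)
}

#' Plaque wall-inset profile
#'
#' Per-wall cosine bump: \deqn{\mathrm{inset}(s) = \frac{d\,w}{2}\cdot
#' \frac{1 + \cos(2\pi (s - c)/L)}{2}} for \eqn{|s - c| \le L/2} and zero
#' outside, where `d` is the occlusion degree, `w` the local channel width,
#' `c` the bump center and `L` its length. The profile and its slope vanish
#' at the bump ends (C1-continuous); its integral is \eqn{d\,w\,L/4}. This is
#' the per-wall half of the occlusion: [build_scenario()] places twice this
#' inset on the plaque-bearing wall so that the throat width is
#' \eqn{(1-d)\,w}.
#'
#' @param s Arc-length coordinate(s) along the branch centerline, m.
#' @param spec A [stenosis_spec()].
#' @param width Local channel width `w`, m.
#' @return Wall inset(s), m.
#' @export
stenosis_profile <- function(s, spec, width) {
  amp <- spec$degree * width / 2
  out <- numeric(length(s))
  inside <- abs(s - spec$center_offset) <= spec$length / 2
  out[inside] <- amp *
    (1 + cos(2 * pi * (s[inside] - spec$center_offset) / spec$length)) / 2
  out
}

# total one-sided inset applied by the mesher (both per-wall halves folded
# onto the plaque side, so the throat realises the full occlusion degree)
total_inset <- function(s, stenoses, branch, width, side) {
  out <- numeric(length(s))
  for (st in stenoses) {
    if (st$branch == branch && st$side == side)
      out <- out + 2 * stenosis_profile(s, st, width)
  }
  out
}

# ---------------------------------------------------------------------------
# mesh construction helpers

# strip block: stations of cross-lines from A_i (wall A) to B_i (wall B);
# returns nodes (row-major by station) and triangles (local 1-based indices)
strip_block <- function(Apts, Bpts, nt) {
  ns <- nrow(Apts) - 1L
  nodes <- matrix(0, (ns + 1L) * (nt + 1L), 2L)
  for (i in 0:ns) {
    tvals <- (0:nt) / nt
    row <- cbind(Apts[i + 1L, 1] + tvals * (Bpts[i + 1L, 1] - Apts[i + 1L, 1]),
                 Apts[i + 1L, 2] + tvals * (Bpts[i + 1L, 2] - Apts[i + 1L, 2]))
    nodes[i * (nt + 1L) + 1:(nt + 1L), ] <- row
  }
  tri <- matrix(0L, 2L * ns * nt, 3L)
  k <- 0L
  for (i in 0:(ns - 1L)) for (j in 0:(nt - 1L)) {
    n00 <- i * (nt + 1L) + j + 1L
    n10 <- n00 + (nt + 1L)
    tri[k + 1L, ] <- c(n00, n10, n10 + 1L)
    tri[k + 2L, ] <- c(n00, n10 + 1L, n00 + 1L)
    k <- k + 2L
  }
  list(nodes = nodes, tri = tri)
}

# triangle patch on (V0,V1,V2) with nt divisions per edge; boundary rows are
# forced to the exact shared chord node arrays for conformal merging
junction_triangle <- function(e01, e02, e12, nt) {
  # e01: nodes V0->V1, e02: V0->V2, e12: V1->V2 (each (nt+1) x 2)
  V0 <- e01[1, ]; V1 <- e01[nt + 1, ]; V2 <- e02[nt + 1, ]
  id <- function(i, j) {            # i along V0->V1, j along V0->V2, i+j<=nt
    # row-major enumeration of the triangular lattice
    prev <- if (i == 0) 0L else sum((nt + 1L) - 0:(i - 1L))
    as.integer(prev + j + 1L)
  }
  npts <- (nt + 1L) * (nt + 2L) / 2L
  nodes <- matrix(0, npts, 2L)
  for (i in 0:nt) for (j in 0:(nt - i)) {
    p <- if (j == 0) e01[i + 1L, ]
    else if (i == 0) e02[j + 1L, ]
    else if (i + j == nt) e12[j + 1L, ]
    else V0 + (i / nt) * (V1 - V0) + (j / nt) * (V2 - V0)
    nodes[id(i, j), ] <- p
  }
  tri <- matrix(0L, nt * nt, 3L)
  k <- 0L
  for (i in 0:(nt - 1L)) for (j in 0:(nt - 1L - i)) {
    k <- k + 1L
    tri[k, ] <- c(id(i, j), id(i + 1L, j), id(i, j + 1L))
    if (i + j <= nt - 2L) {
      k <- k + 1L
      tri[k, ] <- c(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
    }
  }
  list(nodes = nodes, tri = tri[seq_len(k), , drop = FALSE])
}

# bilinear quad patch with forced edge arrays; ex0: eta=0 row (xi 0..nt),
# ex1: eta=1 row, ey0: xi=0 column, ey1: xi=1 column
junction_quad <- function(ex0, ex1, ey0, ey1, nt, nh) {
  id <- function(i, j) as.integer(j * (nt + 1L) + i + 1L)
  nodes <- matrix(0, (nt + 1L) * (nh + 1L), 2L)
  C00 <- ex0[1, ]; C10 <- ex0[nt + 1, ]; C01 <- ex1[1, ]; C11 <- ex1[nt + 1, ]
  for (j in 0:nh) for (i in 0:nt) {
    p <- if (j == 0) ex0[i + 1L, ]
    else if (j == nh) ex1[i + 1L, ]
    else if (i == 0) ey0[j + 1L, ]
    else if (i == nt) ey1[j + 1L, ]
    else {
      xi <- i / nt; eta <- j / nh
      (1 - eta) * ex0[i + 1L, ] + eta * ex1[i + 1L, ] +
        (1 - xi) * ey0[j + 1L, ] + xi * ey1[j + 1L, ] -
        ((1 - xi) * (1 - eta) * C00 + xi * (1 - eta) * C10 +
           (1 - xi) * eta * C01 + xi * eta * C11)
    }
    nodes[id(i, j), ] <- p
  }
  tri <- matrix(0L, 2L * nt * nh, 3L)
  k <- 0L
  for (j in 0:(nh - 1L)) for (i in 0:(nt - 1L)) {
    tri[k + 1L, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
    tri[k + 2L, ] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
    k <- k + 2L
  }
  list(nodes = nodes, tri = tri)
}

# polar sac block: boundary loop b (nb x 2, closed implicitly), center O,
# K radial rings; ring K coincides exactly with b
sac_block <- function(bloop, O, K) {
  nb <- nrow(bloop)
  id_ring <- function(j, k) as.integer(1L + (j - 1L) * nb + ((k - 1L) %% nb) + 1L)
  nodes <- matrix(0, 1L + K * nb, 2L)
  nodes[1L, ] <- O
  for (j in 1:K) for (k in 1:nb) {
    nodes[id_ring(j, k), ] <- if (j == K) bloop[k, ]
    else O + (j / K) * (bloop[k, ] - O)
  }
  tri <- matrix(0L, nb + 2L * nb * (K - 1L), 3L)
  m <- 0L
  for (k in 1:nb) {                     # center fan
    m <- m + 1L
    tri[m, ] <- c(1L, id_ring(1L, k), id_ring(1L, k + 1L))
  }
  if (K > 1) for (j in 1:(K - 1L)) for (k in 1:nb) {
    tri[m + 1L, ] <- c(id_ring(j, k), id_ring(j + 1L, k), id_ring(j + 1L, k + 1L))
    tri[m + 2L, ] <- c(id_ring(j, k), id_ring(j + 1L, k + 1L), id_ring(j, k + 1L))
    m <- m + 2L
  }
  list(nodes = nodes, tri = tri)
}

merge_blocks <- function(blocks) {
  allnodes <- do.call(rbind, lapply(blocks, `[[`, "nodes"))
  key <- paste(sprintf("%.17g", allnodes[, 1]), sprintf("%.17g", allnodes[, 2]))
  uk <- !duplicated(key)
  nodes <- allnodes[uk, , drop = FALSE]
  gid <- match(key, key[uk])
  off <- 0L
  tri_all <- list()
  for (b in blocks) {
    nb <- nrow(b$nodes)
    tri_all[[length(tri_all) + 1L]] <-
      matrix(gid[off + as.integer(b$tri)], ncol = 3L)
    off <- off + nb
  }
  tri <- do.call(rbind, tri_all)
  # drop degenerate (merged-vertex) triangles, orient CCW
  ax <- nodes[tri[, 1], 1]; ay <- nodes[tri[, 1], 2]
  bx <- nodes[tri[, 2], 1]; by <- nodes[tri[, 2], 2]
  cx <- nodes[tri[, 3], 1]; cy <- nodes[tri[, 3], 2]
  area2 <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  keep <- abs(area2) > 0
  tri <- tri[keep, , drop = FALSE]
  flip <- area2[keep] < 0
  tri[flip, ] <- tri[flip, c(1L, 3L, 2L)]
  list(nodes = nodes, tri = tri)
}

tri_areas <- function(nodes, tri) {
  ax <- nodes[tri[, 1], 1]; ay <- nodes[tri[, 1], 2]
  bx <- nodes[tri[, 2], 1]; by <- nodes[tri[, 2], 2]
  cx <- nodes[tri[, 3], 1]; cy <- nodes[tri[, 3], 2]
  0.5 * ((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
}

boundary_edges_of <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bnd <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  bnd
}

# ---------------------------------------------------------------------------

#' Build the tagged triangular mesh for a scenario
#'
#' Deterministic block-structured construction: a parent strip, a transfinite
#' junction patch at the bifurcation, two daughter strips (the second an exact
#' mirror of the first), and for the ACA scenario a polar patch for the
#' saccular sac. Stenoses enter as one-sided cosine wall insets realizing the
#' full occlusion degree at the throat. Boundary edges are tagged `INLET`,
#' `OUTLET_1`, `OUTLET_2` and `WALL`; wall nodes carry a thickness map
#' (sac vs artery, linearly blended over the neck band), a local vessel
#' radius and the curvature kind (cylindrical artery / spherical sac) used by
#' the wall model. The coordinate origin is the bifurcation apex with the
#' parent axis along `-x`; all units SI.
#'
#' @param spec A [scenario_spec()].
#' @return A `fsi_mesh` object: `nodes` (N x 2), `tri` (M x 3, 1-based,
#'   counter-clockwise), `boundary_edges`, `boundary_tag`, per-wall-node
#'   attributes, `target` node ids and `ports` metadata.
#' @export
build_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  W <- spec$parent_diameter
  w <- spec$daughter_diameter
  th <- spec$bifurcation_half_angle * pi / 180
  Lp <- spec$parent_length
  Ld <- spec$daughter_length
  hs <- spec$mesh_size
  nt <- max(6L, as.integer(round(W / hs)))

  u1 <- c(cos(th), sin(th))            # daughter-1 centerline direction
  n1 <- c(-sin(th), cos(th))           # its left (outer) normal
  xJ <- -(w / 2) / sin(th)             # centerline junction point
  J <- c(xJ, 0)
  A <- c(0, 0)                         # carina apex
  sT <- (W / 2 - (w / 2) * cos(th)) / sin(th)
  T1 <- J + sT * u1 + (w / 2) * n1     # parent top wall meets daughter-1 outer wall
  B1 <- c(T1[1], -T1[2])
  if (T1[1] >= -1e-6)
    stop("self-intersecting geometry: daughter width/angle incompatible with parent")
  s_apex_on_cl <- (w / 2) / tan(th)    # centerline coordinate of the apex

  aca <- spec$scenario == "ACA"
  if (aca) {
    aa <- (spec$sac_neck_width / 2) / sin(th)
    N1 <- A + aa * u1                  # neck corner on daughter-1 inner wall
    N2 <- c(N1[1], -N1[2])
    R <- spec$sac_radius
    half_neck <- spec$sac_neck_width / 2
    if (half_neck >= R)
      stop("self-intersecting geometry: sac neck wider than sac diameter")
    O <- c(N1[1] + sqrt(R^2 - half_neck^2), 0)
    inner_start1 <- N1
  } else {
    inner_start1 <- A
  }

  # daughter-1 outlet cross-section (perpendicular to the centerline)
  Lcl <- Ld + s_apex_on_cl
  Cout <- J + Lcl * u1
  OcA <- Cout + (w / 2) * n1           # outer corner
  OcB <- Cout - (w / 2) * n1           # inner corner
  if (length(spec$stenoses)) {
    for (st in spec$stenoses) {
      L_branch <- if (st$branch == "PARENT") Lp + T1[1] else Ld
      if (st$center_offset - st$length / 2 <= 0 ||
          st$center_offset + st$length / 2 >= L_branch)
        stop("stenosis bump does not lie fully inside its branch")
      if (st$degree >= 1) stop("self-intersecting geometry: degree >= 1")
    }
  }

  # ---- shared interface node arrays (exact conformity between blocks) ----
  tvals <- (0:nt) / nt
  lin <- function(P, Q) cbind(P[1] + tvals * (Q[1] - P[1]),
                              P[2] + tvals * (Q[2] - P[2]))
  tb_nodes <- lin(T1, B1)              # parent terminal chord
  ta_nodes <- lin(T1, inner_start1)    # daughter-1 start chord
  ba_nodes <- cbind(ta_nodes[, 1], -ta_nodes[, 2])  # exact mirror

  blocks <- list()

  # ---- parent strip ----
  ns_p <- max(4L, as.integer(round((T1[1] + Lp) / hs)))
  xs <- -Lp + (0:ns_p) / ns_p * (T1[1] + Lp)
  xs[ns_p + 1L] <- T1[1]
  s_par <- -xs                         # distance upstream of the apex
  insA <- total_inset(s_par, spec$stenoses, "PARENT", W, "WALL_A")
  insB <- total_inset(s_par, spec$stenoses, "PARENT", W, "WALL_B")
  Apts <- cbind(xs,  W / 2 - insA)
  Bpts <- cbind(xs, -W / 2 + insB)
  Apts[ns_p + 1L, ] <- T1; Bpts[ns_p + 1L, ] <- B1
  blocks$parent <- strip_block(Apts, Bpts, nt)

  # ---- junction patch ----
  if (!aca) {
    blocks$junction <- junction_triangle(tb_nodes, ta_nodes, ba_nodes, nt)
  } else {
    sc_nodes <- lin(N1, N2)            # sac neck chord
    nh <- max(2L, as.integer(round(sqrt(sum((N1 - T1)^2)) / hs)))
    tn1 <- ta_nodes
    bn2 <- ba_nodes
    blocks$junction <- junction_quad(tb_nodes, sc_nodes, tn1, bn2, nt, nh)
  }

  # ---- daughter-1 strip (then exact mirror for daughter 2) ----
  ns_d <- max(4L, as.integer(round(Ld / hs)))
  svals <- (0:ns_d) / ns_d
  Apts_d <- t(sapply(svals, function(s) T1 + s * (OcA - T1)))
  Bpts_d <- t(sapply(svals, function(s) inner_start1 + s * (OcB - inner_start1)))
  Apts_d[1L, ] <- T1; Bpts_d[1L, ] <- inner_start1
  # centerline arc-length of each station (from the apex)
  mids <- (Apts_d + Bpts_d) / 2
  s_d <- (mids[, 1] - J[1]) * u1[1] + (mids[, 2] - J[2]) * u1[2] - s_apex_on_cl
  iA <- total_inset(s_d, spec$stenoses, "DAUGHTER_1", w, "WALL_A")
  iB <- total_inset(s_d, spec$stenoses, "DAUGHTER_1", w, "WALL_B")
  cdir <- (Bpts_d - Apts_d) / sqrt(rowSums((Bpts_d - Apts_d)^2))
  Ad <- Apts_d + cdir * iA
  Bd <- Bpts_d - cdir * iB
  blocks$daughter1 <- strip_block(Ad, Bd, nt)

  # daughter 2: mirror of daughter 1 unless it carries different stenoses
  iA2 <- total_inset(s_d, spec$stenoses, "DAUGHTER_2", w, "WALL_A")
  iB2 <- total_inset(s_d, spec$stenoses, "DAUGHTER_2", w, "WALL_B")
  Ad2 <- cbind(Apts_d[, 1], -Apts_d[, 2]) + cbind(cdir[, 1], -cdir[, 2]) * iA2
  Bd2 <- cbind(Bpts_d[, 1], -Bpts_d[, 2]) - cbind(cdir[, 1], -cdir[, 2]) * iB2
  blocks$daughter2 <- strip_block(Ad2, Bd2, nt)

  # ---- sac polar patch ----
  if (aca) {
    phiN <- atan2(half_neck, N1[1] - O[1])      # ~> pi/2 (chord behind center)
    na <- max(8L, as.integer(round(2 * phiN * R / hs)))
    phis <- -phiN + (1:(na - 1L)) / na * (2 * phiN)
    arc <- cbind(O[1] + R * cos(phis), O[2] + R * sin(phis))
    bloop <- rbind(sc_nodes,                    # N1 -> N2 down the chord
                   arc)                         # N2 -> N1 around the sac
    K <- max(3L, as.integer(round(R / hs)))
    blocks$sac <- sac_block(bloop, O, K)
  }

  mm <- merge_blocks(blocks)
  nodes <- mm$nodes; tri <- mm$tri
  if (any(tri_areas(nodes, tri) <= 0)) stop("mesh construction produced inverted triangles")

  # ---- boundary extraction and tagging ----
  bnd <- boundary_edges_of(tri)
  mid <- (nodes[bnd[, 1], , drop = FALSE] + nodes[bnd[, 2], , drop = FALSE]) / 2
  tol <- 1e-9
  Cout2 <- c(Cout[1], -Cout[2])
  u2 <- c(u1[1], -u1[2])
  d_out1 <- abs((mid[, 1] - Cout[1]) * u1[1] + (mid[, 2] - Cout[2]) * u1[2])
  d_out2 <- abs((mid[, 1] - Cout2[1]) * u2[1] + (mid[, 2] - Cout2[2]) * u2[2])
  tag <- rep("WALL", nrow(bnd))
  tag[abs(mid[, 1] + Lp) < tol] <- "INLET"
  tag[d_out1 < tol] <- "OUTLET_1"
  tag[d_out2 < tol] <- "OUTLET_2"

  # outward edge normals (away from the adjacent triangle)
  ev <- nodes[bnd[, 2], , drop = FALSE] - nodes[bnd[, 1], , drop = FALSE]
  nrm <- cbind(ev[, 2], -ev[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # orient: opposite to vector towards the third vertex of the owning triangle
  eown <- edge_owner_tri(tri, bnd)
  cent <- (nodes[tri[eown, 1], , drop = FALSE] + nodes[tri[eown, 2], , drop = FALSE] +
             nodes[tri[eown, 3], , drop = FALSE]) / 3
  sgn <- sign(rowSums((mid - cent) * nrm))
  nrm <- nrm * sgn

  # ---- per-wall-node attributes ----
  wall_edge <- tag == "WALL"
  wall_nodes <- sort(unique(as.integer(bnd[wall_edge, ])))
  mat_thk <- rep(NA_real_, nrow(nodes))
  loc_rad <- rep(NA_real_, nrow(nodes))
  kind <- rep(NA_integer_, nrow(nodes))
  thA <- 125e-6; thS <- 27e-6   # defaults; overridden via wall_interface(mat=)
  # centerline segments for the local-radius map
  cl <- list(list(P = c(-Lp, 0), Q = c(xJ + s_apex_on_cl * u1[1], 0)),
             list(P = J + s_apex_on_cl * u1, Q = Cout),
             list(P = c(J[1] + s_apex_on_cl * u2[1], -(J[2] + s_apex_on_cl * u1[2])),
                  Q = Cout2))
  on_sac <- rep(FALSE, nrow(nodes))
  if (aca) {
    dO <- sqrt((nodes[, 1] - O[1])^2 + (nodes[, 2] - O[2])^2)
    on_sac <- abs(dO - R) < 1e-9
  }
  for (v in wall_nodes) {
    if (aca && on_sac[v]) {
      kind[v] <- 2L
      loc_rad[v] <- R
    } else {
      kind[v] <- 1L
      loc_rad[v] <- max(dist_to_centerlines(nodes[v, ], cl), w / 4)
    }
  }
  # thickness map with linear blend over the neck band (on the sac side)
  band <- 0.3e-3
  thk_n <- rep(thA, nrow(nodes))
  sac_blend <- rep(0, nrow(nodes))      # 0 = artery thickness, 1 = sac
  if (aca) {
    phi_v <- atan2(nodes[, 2] - O[2], nodes[, 1] - O[1])
    darc <- (phiN - abs(phi_v)) * R     # arc distance from the nearer neck corner
    sacsel <- on_sac
    blendf <- pmin(pmax(darc[sacsel] / band, 0), 1)
    sac_blend[sacsel] <- blendf
    thk_n[sacsel] <- thA + (thS - thA) * blendf
  }
  mat_thk[wall_nodes] <- thk_n[wall_nodes]

  # ---- target points ----
  tp <- c(apex = nearest_node(nodes, wall_nodes, A))
  if (aca) {
    vert <- c(O[1] + R, 0)
    tp <- c(tp, sac_vertex = nearest_node(nodes, wall_nodes, vert))
    tp["apex"] <- nearest_node(nodes, wall_nodes, c(N1[1], 0))  # neck midline
  }

  ports <- list(
    INLET = list(center = c(-Lp, 0), normal = c(-1, 0), width = W,
                 flow_dir = c(1, 0)),
    OUTLET_1 = list(center = Cout, normal = u1, width = w, flow_dir = u1),
    OUTLET_2 = list(center = Cout2, normal = u2, width = w, flow_dir = u2))

  structure(list(nodes = nodes, tri = tri,
                 boundary_edges = bnd, boundary_tag = tag,
                 boundary_normal = nrm,
                 wall_nodes = wall_nodes,
                 wall_thickness = mat_thk,
                 wall_sac_blend = sac_blend,
                 wall_local_radius = loc_rad,
                 wall_kind = kind,
                 target = tp,
                 ports = ports,
                 geom = list(T1 = T1, B1 = B1, apex = A,
                             sac_center = if (aca) O else NULL,
                             sac_phiN = if (aca) phiN else NULL,
                             J = J, u1 = u1, u2 = u2,
                             s_apex_on_cl = s_apex_on_cl),
                 spec = spec),
            class = "fsi_mesh")
}

edge_owner_tri <- function(tri, edges) {
  keyt <- c(paste(pmin(tri[, 1], tri[, 2]), pmax(tri[, 1], tri[, 2])),
            paste(pmin(tri[, 2], tri[, 3]), pmax(tri[, 2], tri[, 3])),
            paste(pmin(tri[, 3], tri[, 1]), pmax(tri[, 3], tri[, 1])))
  owner <- rep(seq_len(nrow(tri)), 3L)
  keye <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  owner[match(keye, keyt)]
}

dist_to_centerlines <- function(p, cl) {
  dmin <- Inf
  for (seg in cl) {
    v <- seg$Q - seg$P
    t <- sum((p - seg$P) * v) / sum(v * v)
    t <- min(max(t, 0), 1)
    d <- sqrt(sum((seg$P + t * v - p)^2))
    dmin <- min(dmin, d)
  }
  dmin
}

nearest_node <- function(nodes, subset, p) {
  d <- (nodes[subset, 1] - p[1])^2 + (nodes[subset, 2] - p[2])^2
  subset[which.min(d)]
}

#' @export
print.fsi_mesh <- function(x, ...) {
  cat(sprintf("fsi_mesh (%s): %d nodes, %d triangles, %d boundary edges\n",
              x$spec$scenario, nrow(x$nodes), nrow(x$tri),
              nrow(x$boundary_edges)))
  cat("  boundary tags:", paste(sprintf("%s=%d", names(table(x$boundary_tag)),
                                        table(x$boundary_tag)), collapse = " "), "\n")
  cat("  target points:", paste(sprintf("%s=%d", names(x$target), x$target),
                                collapse = " "), "\n")
  invisible(x)
}

#' Named target-point node ids of a mesh
#'
#' The measurement locations of the study: the wall node at the middle of the
#' bifurcation (apex) for all scenarios, plus the vertex of the sac for the
#' aneurysm scenario. Ids are stable under refinement (nearest-node snap to
#' the analytic locations).
#'
#' @param mesh A [build_scenario()] mesh.
#' @param spec The [scenario_spec()] the mesh was built from (defaults to the
#'   one stored in the mesh).
#' @return Named integer vector of node ids.
#' @export
target_points <- function(mesh, spec = mesh$spec) {
  tp <- mesh$target
  if (spec$scenario != "ACA" && "sac_vertex" %in% names(tp))
    stop("internal inconsistency: sac target on non-ACA mesh")
  tp
}

#' Fetch one target node id by name
#' @param mesh A [build_scenario()] mesh.
#' @param name `"apex"` or `"sac_vertex"`.
#' @return Integer node id.
#' @export
target_node <- function(mesh, name) {
  tp <- mesh$target
  if (!name %in% names(tp))
    stop(sprintf("target '%s' not defined for scenario %s", name,
                 mesh$spec$scenario))
  unname(tp[name])
}

#' Uniformly refine a scenario mesh
#'
#' Rebuilds the mesh from its stored spec with the target element size
#' divided by `factor` (the construction is parametric, so refinement is a
#' re-mesh, preserving all invariants and snapping target points to the same
#' analytic locations).
#'
#' @param mesh A [build_scenario()] mesh.
#' @param factor Size-reduction factor (> 0); `2` roughly quadruples the
#'   triangle count.
#' @return A new `fsi_mesh`.
#' @export
refine <- function(mesh, factor) {
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0")
  spec <- mesh$spec
  spec$mesh_size <- spec$mesh_size / factor
  build_scenario(spec)
}

#' Straight-channel validation mesh
#'
#' Plane channel of the given length and width with `INLET` at `x = 0`,
#' `OUTLET_1` at `x = length` and walls at `y = +-width/2`; same mesh data
#' structure as the scenario meshes. Used to validate the flow solver against
#' the analytic plane-Poiseuille oracle.
#'
#' @param length Channel length, m.
#' @param width Channel gap, m.
#' @param mesh_size Target element size, m.
#' @return An `fsi_mesh` object (scenario tag `"CHANNEL"`).
#' @export
build_channel <- function(length = 12e-3, width = 3.2e-3, mesh_size = 2.5e-4) {
  nt <- max(6L, as.integer(round(width / mesh_size)))
  ns <- max(4L, as.integer(round(length / mesh_size)))
  xs <- (0:ns) / ns * length
  Apts <- cbind(xs, rep(width / 2, ns + 1L))
  Bpts <- cbind(xs, rep(-width / 2, ns + 1L))
  blk <- strip_block(Apts, Bpts, nt)
  mm <- merge_blocks(list(blk))
  nodes <- mm$nodes; tri <- mm$tri
  bnd <- boundary_edges_of(tri)
  mid <- (nodes[bnd[, 1], , drop = FALSE] + nodes[bnd[, 2], , drop = FALSE]) / 2
  tol <- 1e-9
  tag <- rep("WALL", nrow(bnd))
  tag[abs(mid[, 1]) < tol] <- "INLET"
  tag[abs(mid[, 1] - length) < tol] <- "OUTLET_1"
  ev <- nodes[bnd[, 2], , drop = FALSE] - nodes[bnd[, 1], , drop = FALSE]
  nrm <- cbind(ev[, 2], -ev[, 1]); nrm <- nrm / sqrt(rowSums(nrm^2))
  eown <- edge_owner_tri(tri, bnd)
  cent <- (nodes[tri[eown, 1], , drop = FALSE] + nodes[tri[eown, 2], , drop = FALSE] +
             nodes[tri[eown, 3], , drop = FALSE]) / 3
  nrm <- nrm * sign(rowSums((mid - cent) * nrm))
  wall_nodes <- sort(unique(as.integer(bnd[tag == "WALL", ])))
  thk <- rep(NA_real_, nrow(nodes)); thk[wall_nodes] <- 125e-6
  rad <- rep(NA_real_, nrow(nodes)); rad[wall_nodes] <- width / 2
  knd <- rep(NA_integer_, nrow(nodes)); knd[wall_nodes] <- 1L
  mid_wall <- nearest_node(nodes, wall_nodes, c(length / 2, width / 2))
  spec <- list(scenario = "CHANNEL", mesh_size = mesh_size,
               parent_diameter = width, parent_length = length,
               stenoses = list(), sac_radius = 0, seed = 1L)
  structure(list(nodes = nodes, tri = tri, boundary_edges = bnd,
                 boundary_tag = tag, boundary_normal = nrm,
                 wall_nodes = wall_nodes, wall_thickness = thk,
                 wall_sac_blend = rep(0, nrow(nodes)),
                 wall_local_radius = rad, wall_kind = knd,
                 target = c(mid_wall = mid_wall),
                 ports = list(
                   INLET = list(center = c(0, 0), normal = c(-1, 0),
                                width = width, flow_dir = c(1, 0)),
                   OUTLET_1 = list(center = c(length, 0), normal = c(1, 0),
                                   width = width, flow_dir = c(1, 0))),
                 geom = list(), spec = spec),
            class = "fsi_mesh")
}

# structural validity used by tests and after morphing
validate_mesh <- function(mesh) {
  areas <- tri_areas(mesh$nodes, mesh$tri)
  if (any(areas <= 0)) return("inverted or degenerate triangles")
  bnd <- mesh$boundary_edges
  deg <- table(as.integer(bnd))
  if (any(deg != 2L)) return("boundary is not a closed 1-manifold")
  if (length(mesh$boundary_tag) != nrow(bnd)) return("tag/edge length mismatch")
  if (!all(mesh$boundary_tag %in% c("INLET", "OUTLET_1", "OUTLET_2", "WALL")))
    return("unknown boundary tag")
  TRUE
}

# ---------------------------------------------------------------------------
# serialization

#' Write a mesh (and optional nodal fields) as VTK legacy ASCII
#'
#' Unstructured-grid VTK legacy format, 0-based connectivity, fixed number
#' formatting so that identical meshes produce byte-identical files.
#'
#' @param mesh A [build_scenario()] mesh.
#' @param path Output file path.
#' @param point_data Named list of per-node scalar vectors or 2-column
#'   matrices (written as 3-vectors with zero z).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con, sep = "\n")
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  wl("# vtk DataFile Version 3.0")
  wl("cerebrofsi mesh (%s)", mesh$spec$scenario)
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", n)
  writeLines(sprintf("%.12e %.12e 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  wl("CELLS %d %d", m, 4L * m)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  wl("CELL_TYPES %d", m)
  writeLines(rep("5", m), con)
  if (!is.null(point_data) && length(point_data)) {
    wl("POINT_DATA %d", n)
    for (nmf in names(point_data)) {
      v <- point_data[[nmf]]
      if (is.matrix(v)) {
        wl("VECTORS %s double", nmf)
        writeLines(sprintf("%.12e %.12e 0", v[, 1], v[, 2]), con)
      } else {
        wl("SCALARS %s double 1", nmf)
        wl("LOOKUP_TABLE default")
        writeLines(sprintf("%.12e", v), con)
      }
    }
  }
  invisible(path)
}

#' Write the JSON sidecar of a mesh (tags, thickness map, target points)
#'
#' @param mesh A [build_scenario()] mesh.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_sidecar <- function(mesh, path) {
  side <- list(
    scenario = mesh$spec$scenario,
    n_nodes = nrow(mesh$nodes),
    n_triangles = nrow(mesh$tri),
    boundary_tags = as.list(table(mesh$boundary_tag)),
    # 0-based ids in serialized form, matching the VTK connectivity
    target_points = as.list(mesh$target - 1L),
    wall_thickness = list(nodes_0based = mesh$wall_nodes - 1L,
                          thickness_m = mesh$wall_thickness[mesh$wall_nodes]),
    mesh_size = mesh$spec$mesh_size,
    seed = mesh$spec$seed)
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
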