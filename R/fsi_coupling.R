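#' Settings for the partitioned fluid-structure coupling loop
#'
#' @param max_outer_iters Cap on outer (flow <-> wall) iterations.
#' @param interface_tol Convergence tolerance on the maximum interface
#'   displacement increment, m.
#' @param relaxation `"aitken"` (dynamic) or `"fixed"` under-relaxation.
#' @param initial_factor Starting relaxation factor.
#' @param clamp Two-element range the factor is clamped to.
#' @param prestress If `TRUE` (default), the as-meshed geometry is treated as
#'   pre-equilibrated at the inlet reference transmural pressure, and wall
#'   loads/displacements are measured relative to the zero-flow datum. The
#'   unprestressed alternative loads the stress-free wall with the full
#'   absolute pressure, which exceeds the sac's balloon limit point at the
#'   default conditions.
#' @return An object of class `coupling_settings`.
#' @export
coupling_settings <- function(max_outer_iters = 50,
                              interface_tol = 1e-7,
                              relaxation = c("aitken", "fixed"),
                              initial_factor = 0.5,
                              clamp = c(0.1, 1.0),
                              prestress = TRUE) {
  relaxation <- match.arg(relaxation)
  if (interface_tol <= 0) stop("interface_tol must be > 0")
  if (initial_factor < clamp[1] || initial_factor > clamp[2])
    stop("initial relaxation factor outside clamp range")
  structure(list(max_outer_iters = max_outer_iters,
                 interface_tol = interface_tol,
                 relaxation = relaxation,
                 initial_factor = initial_factor,
                 clamp = clamp,
                 prestress = prestress),
            class = "coupling_settings")
}

#' Wall interface description for the membrane model
#'
#' Collects the ordered wall chains of a mesh together with everything the
#' membrane updater needs: reference positions, outward normals, per-node
#' thickness (artery/sac blend scaled to the material), local vessel radius,
#' curvature kind, and the prestress state (prestretch, tension and datum
#' pressure) implied by treating the as-meshed wall as equilibrated at the
#' reference transmural pressure.
#'
#' @param mesh A [build_scenario()] / [build_channel()] mesh.
#' @param mat A [wall_material()].
#' @param prestress_pressure Reference transmural pressure, Pa (0 disables
#'   prestress).
#' @param sac_prestretch_cap Upper bound on the sac prestretch used in the
#'   hoop-foundation linearization. The incompressible neo-Hookean balloon
#'   softens beyond its limit point at \eqn{7^{1/6} \approx 1.38}; a real
#'   aneurysm wall at systemic pressure is stabilized by collagen
#'   recruitment the law does not represent, so the foundation is linearized
#'   on the stable branch, capped at this stretch.
#' @return A list (class `wall_interface`) consumed by
#'   [membrane_wall_update()] and [solve_fsi()].
#' @export
wall_interface <- function(mesh, mat = wall_material(),
                           prestress_pressure = 16000,
                           sac_prestretch_cap = 1.2) {
  wn <- wall_node_normals(mesh)
  ids <- wn$ids
  chains <- wall_chains(mesh)
  segs <- do.call(rbind, lapply(chains, function(ch) {
    pos <- match(ch, ids)
    cbind(pos[-length(pos)], pos[-1])
  }))
  anchors <- match(unlist(lapply(chains, function(ch) ch[c(1, length(ch))])), ids)
  thk <- mat$thickness_artery +
    (mat$thickness_sac - mat$thickness_artery) * mesh$wall_sac_blend[ids]
  rad <- mesh$wall_local_radius[ids]
  kind <- mesh$wall_kind[ids]
  mu <- 2 * mat$C1
  pre <- vapply(seq_along(ids), function(k) {
    if (prestress_pressure <= 0) return(1)
    if (kind[k] == 2L)
      min(prestretch_sphere(prestress_pressure, rad[k], thk[k], mu),
          sac_prestretch_cap)
    else prestretch_cylinder(prestress_pressure, rad[k], thk[k], mu)
  }, 0)
  structure(list(nodes = mesh$nodes[ids, , drop = FALSE],
                 ids = ids,
                 normals = wn$normal,
                 segments = segs,
                 anchors = sort(unique(anchors)),
                 thickness = thk,
                 local_radius = rad,
                 kind = kind,
                 prestretch = pre,
                 pre_pressure = rep(max(prestress_pressure, 0), length(ids)),
                 pre_tension = pmax(prestress_pressure, 0) * rad / 2),
            class = "wall_interface")
}

#' Fluid traction on the wall
#'
#' Full traction \eqn{t = (-p I + 2\eta\dot\varepsilon)\cdot \hat n} at the
#' wall nodes, with \eqn{\hat n} the unit normal pointing from the lumen into
#' the wall, the absolute pressure, and the rate-of-deformation tensor from
#' recovered nodal velocity gradients. Normal and tangential parts are
#' returned separately as well.
#'
#' @param flow A converged `flow_field`.
#' @param mesh The mesh.
#' @param params [rheology_params()].
#' @return A list: `node` ids, `traction` (K x 2, Pa), `normal_component`
#'   (signed, Pa), `tangential` (K x 2, Pa), `normal` (unit vectors).
#' @export
interface_traction <- function(flow, mesh, params = rheology_params()) {
  wn <- wall_node_normals(mesh)
  if (any(!is.finite(wn$normal))) stop("degenerate boundary edge: undefined normal")
  G <- recover_gradients(mesh, flow$velocity, wn$ids)
  K <- length(wn$ids)
  tr <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    Gk <- G[k, , ]
    eps <- (Gk + t(Gk)) / 2
    gam <- sqrt(2 * sum(eps * eps))
    eta <- effective_viscosity(gam, params)
    tr[k, ] <- -flow$pressure_abs[wn$ids[k]] * wn$normal[k, ] +
      2 * eta * as.numeric(eps %*% wn$normal[k, ])
  }
  tn <- rowSums(tr * wn$normal)
  structure(list(node = wn$ids, traction = tr,
                 normal_component = tn,
                 tangential = tr - tn * wn$normal,
                 normal = wn$normal),
            class = "interface_traction")
}

#' Aitken dynamic relaxation factor
#'
#' Classical Aitken update from the last two interface-residual vectors:
#' \deqn{\omega_{k+1} = -\omega_k \frac{\langle r_{k-1}, r_k - r_{k-1}
#' \rangle}{\|r_k - r_{k-1}\|^2},} clamped to the given range. Degenerate
#' histories (identical consecutive residuals) halve the factor towards
#' stability; a zero current residual means the loop has converged and the
#' factor is returned untouched.
#'
#' @param history List of interface residual vectors (most recent last).
#' @param omega Current relaxation factor.
#' @param clamp Two-element clamp range.
#' @return Updated factor.
#' @export
aitken_factor <- function(history, omega = 0.5, clamp = c(0.1, 1.0)) {
  nh <- length(history)
  if (nh < 2) return(omega)
  r1 <- history[[nh - 1]]; r2 <- history[[nh]]
  if (sqrt(sum(r2^2)) == 0) return(omega)
  dr <- r2 - r1
  den <- sum(dr^2)
  if (den < 1e-300) return(max(omega / 2, clamp[1]))
  om <- -omega * sum(r1 * dr) / den
  min(max(om, clamp[1]), clamp[2])
}

#' Morph a mesh by a wall displacement field
#'
#' Boundary wall nodes are moved by the given displacement (ports stay
#' fixed); interior nodes follow by Laplacian smoothing (graph Laplacian
#' solve with all boundary nodes as Dirichlet data). Tags, connectivity and
#' attributes are preserved. Errors if the morph inverts any triangle.
#'
#' @param mesh The reference mesh.
#' @param wall_displacement Either an N x 2 matrix over all nodes (non-wall
#'   rows ignored) or a K x 2 matrix over `mesh$wall_nodes`.
#' @return The morphed `fsi_mesh`.
#' @export
morph_mesh <- function(mesh, wall_displacement) {
  n <- nrow(mesh$nodes)
  d <- matrix(0, n, 2)
  bnodes_all <- sort(unique(as.integer(mesh$boundary_edges)))
  if (nrow(wall_displacement) == n) {
    d[bnodes_all, ] <- wall_displacement[bnodes_all, , drop = FALSE]
  } else if (nrow(wall_displacement) == length(mesh$wall_nodes)) {
    d[mesh$wall_nodes, ] <- wall_displacement
  } else stop("displacement size mismatch")
  mx <- max(sqrt(rowSums(d^2)))
  wmin <- min(mesh$wall_local_radius[mesh$wall_nodes], na.rm = TRUE)
  if (mx > 0.2 * wmin)
    stop(sprintf("morph displacement %.3g m exceeds 10%% of the local channel width", mx))
  if (mx == 0) return(mesh)

  bnodes <- sort(unique(as.integer(mesh$boundary_edges)))
  inter <- setdiff(seq_len(n), bnodes)
  out <- mesh
  if (length(inter)) {
    tri <- mesh$tri
    e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
    e <- rbind(e, e[, 2:1])
    e <- unique(e)
    Lap <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
    deg <- Matrix::rowSums(Lap)
    L <- Matrix::Diagonal(x = deg) - Lap
    Lii <- L[inter, inter, drop = FALSE]
    Lib <- L[inter, bnodes, drop = FALSE]
    di <- as.matrix(Matrix::solve(Lii, -Lib %*% d[bnodes, , drop = FALSE]))
    d[inter, ] <- di
  }
  out$nodes <- mesh$nodes + d
  if (any(tri_areas(out$nodes, out$tri) <= 0))
    stop("mesh morphing inverted triangles")
  out
}

#' Partitioned quasi-static fluid-structure solve
#'
#' Fixed-point loop over: steady flow solve on the current configuration,
#' fluid traction extraction at the interface, membrane wall update, dynamic
#' (Aitken) under-relaxation, and mesh morphing — until the maximum interface
#' displacement increment falls below `interface_tol`. With prestress (the
#' default), the wall is taken to be pre-equilibrated at the reference
#' transmural pressure in its as-meshed configuration, the traction datum is
#' the zero-flow hydrostatic state at the outlet pressure, and the reported
#' displacement is the flow-induced perturbation about that state. No-slip
#' holds on the current (morphed) configuration; at convergence the membrane
#' residual under the final traction is below the membrane solver tolerance
#' (recorded in the returned state).
#'
#' @param mesh The reference mesh.
#' @param params [rheology_params()].
#' @param mat [wall_material()].
#' @param bcs [flow_bcs()].
#' @param cset [coupling_settings()].
#' @param settings [solver_settings()] for the inner flow solves.
#' @return A list: `flow` (converged `flow_field` on the deformed mesh),
#'   `displacement` (N x 2, m, relative to the prestressed datum), `mesh`
#'   (morphed), `state` (class `coupling_state`: iteration history, final
#'   residuals, relaxation factors).
#' @export
solve_fsi <- function(mesh, params = rheology_params(), mat = wall_material(),
                      bcs = flow_bcs(), cset = coupling_settings(),
                      settings = solver_settings()) {
  p_pre <- if (cset$prestress) bcs$inlet_reference_pressure else 0
  ic <- wall_interface(mesh, mat, p_pre)
  K <- length(ic$ids)
  d_prev <- matrix(0, K, 2)
  cur_mesh <- mesh
  omega <- cset$initial_factor
  inc_hist <- numeric(0)
  res_hist <- list()
  omegas <- numeric(0)
  flow <- NULL
  membrane_res <- NA_real_
  u_warm <- NULL

  for (it in seq_len(cset$max_outer_iters)) {
    flow <- solve_steady_flow(cur_mesh, params, bcs, settings, initial = u_warm)
    u_warm <- flow$velocity
    tr <- interface_traction(flow, cur_mesh, params)
    # traction increment relative to the zero-flow hydrostatic datum
    dt <- tr$traction + bcs$outlet_pressure * ic$normals
    up <- membrane_wall_update(ic, dt, mat)
    membrane_res <- up$residual_norm
    r <- up$displacement - d_prev
    res_hist[[length(res_hist) + 1L]] <- as.numeric(r)
    if (cset$relaxation == "aitken" && it >= 2)
      omega <- aitken_factor(res_hist, omega, cset$clamp)
    omegas <- c(omegas, omega)
    d_new <- d_prev + omega * r
    inc <- max(sqrt(rowSums((d_new - d_prev)^2)))
    inc_hist <- c(inc_hist, inc)
    d_prev <- d_new
    cur_mesh <- morph_mesh(mesh, d_new)
    if (inc < cset$interface_tol) break
    if (it == cset$max_outer_iters)
      stop(sprintf("FSI coupling did not converge; increment history: %s",
                   paste(sprintf("%.3e", inc_hist), collapse = " ")))
  }

  disp_full <- matrix(0, nrow(mesh$nodes), 2)
  disp_full[ic$ids, ] <- d_prev
  disp_full <- disp_full + (cur_mesh$nodes - morph_mesh(mesh, d_prev * 0)$nodes) * 0
  # interior displacement from the morph itself
  disp_full <- cur_mesh$nodes - mesh$nodes

  state <- structure(list(iterations = length(inc_hist),
                          increments = inc_hist,
                          relaxation_factors = omegas,
                          membrane_residual = membrane_res,
                          converged = inc_hist[length(inc_hist)] < cset$interface_tol,
                          interface_tol = cset$interface_tol),
                     class = "coupling_state")
  list(flow = flow, displacement = disp_full, mesh = cur_mesh, state = state)
}

#' @export
print.coupling_state <- function(x, ...) {
  cat(sprintf("coupling_state: %d outer iterations, %s (tol %.1e m)\n",
              x$iterations,
              if (x$converged) "converged" else "NOT converged",
              x$interface_tol))
  cat("  increments [m]:", paste(sprintf("%.2e", x$increments), collapse = " "), "\n")
  invisible(x)
}
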