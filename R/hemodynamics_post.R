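## Post-processing: wall shear stress extraction, target-point series,
## per-scenario summaries.

# node-to-node adjacency (list of integer vectors) from the triangulation
node_adjacency <- function(mesh) {
  tri <- mesh$tri
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  split(e[, 2], e[, 1])
}

# Recover nodal velocity gradients by a quadratic least-squares fit over the
# two-ring patch of each requested node. Exact for globally quadratic fields,
# which makes the plane-Poiseuille wall shear exact at any resolution.
recover_gradients <- function(mesh, u, node_ids, adj = node_adjacency(mesh)) {
  out <- array(0, dim = c(length(node_ids), 2, 2))
  for (k in seq_along(node_ids)) {
    v <- node_ids[k]
    r1 <- adj[[as.character(v)]]
    patch <- unique(c(v, r1, unlist(adj[as.character(r1)], use.names = FALSE)))
    dx <- mesh$nodes[patch, 1] - mesh$nodes[v, 1]
    dy <- mesh$nodes[patch, 2] - mesh$nodes[v, 2]
    sc <- max(sqrt(dx^2 + dy^2))
    dx <- dx / sc; dy <- dy / sc
    X <- cbind(1, dx, dy, dx^2, dx * dy, dy^2)
    fit <- tryCatch(qr.coef(qr(X), u[patch, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit[2:3, ])) {
      # degenerate patch: fall back to a linear fit
      fit <- qr.coef(qr(X[, 1:3]), u[patch, , drop = FALSE])
      fit <- rbind(fit, matrix(0, 3, ncol(fit)))
    }
    # rows: du/dx, du/dy per component; gradient tensor G[i,j] = dv_i/dx_j
    out[k, 1, 1] <- fit[2, 1] / sc; out[k, 1, 2] <- fit[3, 1] / sc
    out[k, 2, 1] <- fit[2, 2] / sc; out[k, 2, 2] <- fit[3, 2] / sc
  }
  out
}

# per-wall-node outward unit normal and lumped edge length
wall_node_normals <- function(mesh) {
  sel <- which(mesh$boundary_tag == "WALL")
  e <- mesh$boundary_edges[sel, , drop = FALSE]
  nrm <- mesh$boundary_normal[sel, , drop = FALSE]
  len <- sqrt(rowSums((mesh$nodes[e[, 2], , drop = FALSE] -
                         mesh$nodes[e[, 1], , drop = FALSE])^2))
  ids <- mesh$wall_nodes
  nn <- matrix(0, length(ids), 2)
  wl <- numeric(length(ids))
  pos <- match(as.integer(e), ids)
  for (col in 1:2) {
    nn[, col] <- tabulate0(pos, rep(nrm[, col] * len / 2, 2), length(ids))
  }
  wl <- tabulate0(pos, rep(len / 2, 2), length(ids))
  nn <- nn / pmax(sqrt(rowSums(nn^2)), 1e-300)
  list(ids = ids, normal = nn, lumped_length = wl)
}

# ordered chains of wall nodes (each chain runs between two port corners)
wall_chains <- function(mesh) {
  sel <- which(mesh$boundary_tag == "WALL")
  e <- mesh$boundary_edges[sel, , drop = FALSE]
  ids <- sort(unique(as.integer(e)))
  deg <- table(factor(as.integer(e), levels = ids))
  nbr <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(e))) {
    for (dir in 1:2) {
      a <- as.character(e[r, dir]); b <- e[r, 3 - dir]
      assign(a, c(get0(a, envir = nbr, ifnotfound = integer(0)), b), envir = nbr)
    }
  }
  ends <- ids[deg == 1L]
  chains <- list()
  visited <- new.env(hash = TRUE, parent = emptyenv())
  for (s in ends) {
    if (!is.null(get0(as.character(s), envir = visited))) next
    chain <- s
    assign(as.character(s), TRUE, envir = visited)
    cur <- s; prev <- -1L
    repeat {
      nxt <- setdiff(get(as.character(cur), envir = nbr), prev)
      if (!length(nxt)) break
      nxt <- nxt[[1]]
      chain <- c(chain, nxt)
      assign(as.character(nxt), TRUE, envir = visited)
      prev <- cur; cur <- nxt
      if (length(get(as.character(cur), envir = nbr)) < 2L) break
    }
    chains[[length(chains) + 1L]] <- chain
  }
  chains
}

#' Wall shear stress field from a converged flow solution
#'
#' Builds the symmetric rate-of-deformation tensor from recovered nodal
#' velocity gradients on the wall (quadratic least-squares patch recovery),
#' forms the viscous traction \eqn{2\eta\,\dot\varepsilon\cdot\hat n} with the
#' local converged effective viscosity, and subtracts the normal component,
#' leaving the tangential wall-shear-stress vector. The 3D tensor formula
#' reduces to its 2x2 form on the planar reference discretization.
#'
#' @param flow A [solve_steady_flow()] `flow_field`.
#' @param mesh The mesh the flow was solved on.
#' @param params [rheology_params()] (for the viscosity at the recovered
#'   wall shear rate).
#' @return A `wss_field`: `node` (wall node ids), `wss_vector` (K x 2, Pa),
#'   `wss_mag` (Pa), `normal_pressure` (Pa, absolute), `arc_length` (m,
#'   per chain), `chain` (chain index per node), `normal` (outward unit).
#' @export
compute_wss <- function(flow, mesh, params = rheology_params()) {
  if (is.null(flow$viscosity)) stop("flow field carries no viscosity field")
  wn <- wall_node_normals(mesh)
  G <- recover_gradients(mesh, flow$velocity, wn$ids)
  K <- length(wn$ids)
  tx <- numeric(K); ty <- numeric(K); eta_w <- numeric(K)
  for (k in seq_len(K)) {
    Gk <- G[k, , ]
    eps <- (Gk + t(Gk)) / 2
    gam <- sqrt(2 * sum(eps * eps))
    eta_w[k] <- effective_viscosity(gam, params)
    tv <- 2 * eta_w[k] * (eps %*% wn$normal[k, ])
    tx[k] <- tv[1]; ty[k] <- tv[2]
  }
  tn <- tx * wn$normal[, 1] + ty * wn$normal[, 2]
  wx <- tx - tn * wn$normal[, 1]
  wy <- ty - tn * wn$normal[, 2]
  chains <- wall_chains(mesh)
  chain_id <- integer(K); arc <- numeric(K)
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    pos <- match(ch, wn$ids)
    seglen <- sqrt(rowSums((mesh$nodes[ch[-1], , drop = FALSE] -
                              mesh$nodes[ch[-length(ch)], , drop = FALSE])^2))
    arc[pos] <- c(0, cumsum(seglen))
    chain_id[pos] <- ci
  }
  structure(list(node = wn$ids,
                 wss_vector = cbind(wx, wy),
                 wss_mag = sqrt(wx^2 + wy^2),
                 normal_pressure = flow$pressure_abs[wn$ids],
                 viscosity_wall = eta_w,
                 normal = wn$normal,
                 lumped_length = wn$lumped_length,
                 arc_length = arc,
                 chain = chain_id),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("wss_field: %d wall nodes, |WSS| max %.3g Pa, median %.3g Pa\n",
              length(x$node), max(x$wss_mag),
              weighted_median(x$wss_mag, x$lumped_length)))
  invisible(x)
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Time series of fields at a named target point
#'
#' Exact nodal sampling (no interpolation) of velocity magnitude, pressure,
#' displacement magnitude and WSS magnitude at a target node across an
#' ordered sequence of states.
#'
#' @param times Time stamps, s (strictly increasing).
#' @param fields List of `flow_field`s.
#' @param mesh The mesh.
#' @param target Target name (see [target_points()]) or a node id.
#' @param displacements Optional list of N x 2 displacement fields (m),
#'   parallel to `fields`; zero if omitted.
#' @param wss_fields Optional list of `wss_field`s parallel to `fields`; if
#'   omitted the WSS is computed per state.
#' @param params [rheology_params()] used when WSS must be computed.
#' @return A data.frame `time, velocity, pressure, displacement, wss`
#'   (SI units), of class `target_series`.
#' @export
extract_series <- function(times, fields, mesh, target = "apex",
                           displacements = NULL, wss_fields = NULL,
                           params = rheology_params()) {
  if (is.character(target)) target <- target_node(mesh, target)
  if (length(times) != length(fields)) stop("times/fields length mismatch")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  vel <- vapply(fields, function(f) sqrt(sum(f$velocity[target, ]^2)), 0)
  pre <- vapply(fields, function(f) f$pressure_abs[target], 0)
  dis <- if (is.null(displacements)) rep(0, length(times)) else
    vapply(displacements, function(d) sqrt(sum(d[target, ]^2)), 0)
  wssv <- if (is.null(wss_fields)) {
    # single-node extraction: recover the gradient only at the target
    wn <- wall_node_normals(mesh)
    k <- match(target, wn$ids)
    if (is.na(k)) stop("target node is not a wall node")
    adj <- node_adjacency(mesh)
    vapply(fields, function(f) {
      G <- recover_gradients(mesh, f$velocity, target, adj)[1, , ]
      eps <- (G + t(G)) / 2
      eta <- effective_viscosity(sqrt(2 * sum(eps * eps)), params)
      tv <- 2 * eta * as.numeric(eps %*% wn$normal[k, ])
      tn <- sum(tv * wn$normal[k, ])
      sqrt(sum((tv - tn * wn$normal[k, ])^2))
    }, 0)
  } else {
    vapply(wss_fields, function(w) {
      i <- match(target, w$node)
      if (is.na(i)) NA_real_ else w$wss_mag[i]
    }, 0)
  }
  structure(data.frame(time = times, velocity = vel, pressure = pre,
                       displacement = dis, wss = wssv),
            class = c("target_series", "data.frame"))
}

#' Per-scenario summary statistics
#'
#' Wall-wide maximum and edge-length-weighted median WSS, target-point WSS,
#' peak velocity and pressure, and displacement statistics. Medians are
#' weighted by the lumped wall edge length so they are stable under mesh
#' refinement.
#'
#' @param wss A [compute_wss()] field.
#' @param flow The `flow_field`.
#' @param mesh The mesh.
#' @param displacement Optional N x 2 wall displacement field, m.
#' @return A list of named scalars (class `scenario_summary`).
#' @export
summarize_scenario <- function(wss, flow, mesh, displacement = NULL) {
  tgt <- mesh$target
  tgt_wss <- vapply(tgt, function(id) {
    i <- match(id, wss$node)
    if (is.na(i)) NA_real_ else wss$wss_mag[i]
  }, 0)
  names(tgt_wss) <- names(tgt)
  disp_mag <- if (is.null(displacement)) numeric(0) else
    sqrt(rowSums(displacement[wss$node, , drop = FALSE]^2))
  wl <- wss$lumped_length
  out <- list(
    scenario = mesh$spec$scenario,
    n_nodes = nrow(mesh$nodes),
    peak_wss = max(wss$wss_mag),
    median_wss = weighted_median(wss$wss_mag, wl),
    target_wss = tgt_wss,
    peak_velocity = max(sqrt(rowSums(flow$velocity^2))),
    peak_pressure = max(flow$pressure_abs),
    median_displacement = if (length(disp_mag))
      weighted_median(disp_mag, wl) else NA_real_,
    max_displacement = if (length(disp_mag)) max(disp_mag) else NA_real_,
    target_displacement = if (is.null(displacement)) NA_real_ else
      vapply(tgt, function(id) sqrt(sum(displacement[id, ]^2)), 0))
  class(out) <- "scenario_summary"
  out
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat(sprintf("%s: peak WSS %.3g Pa (median %.3g), target WSS %s Pa\n",
              x$scenario, x$peak_wss, x$median_wss,
              paste(sprintf("%s=%.3g", names(x$target_wss), x$target_wss),
                    collapse = ", ")))
  cat(sprintf("  peak |u| %.3g m/s, peak p %.5g Pa", x$peak_velocity,
              x$peak_pressure))
  if (!all(is.na(x$max_displacement)))
    cat(sprintf(", max |d| %.3g mm", x$max_displacement * 1e3))
  cat("\n")
  invisible(x)
}

# minimum WSS along the straight parent wall, excluding nodes within one
# parent diameter of the inlet and of the apex (used in validation reports)
parent_wall_min_wss <- function(wss, mesh) {
  D <- mesh$spec$parent_diameter
  Lp <- mesh$spec$parent_length
  xs <- mesh$nodes[wss$node, 1]
  sel <- xs > (-Lp + D) & xs < -D &
    abs(abs(mesh$nodes[wss$node, 2]) - D / 2) < D / 4
  if (!any(sel)) stop("no parent-wall nodes in the exclusion window")
  min(wss$wss_mag[sel])
}
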