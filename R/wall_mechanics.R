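#' Arterial wall material (incompressible neo-Hookean)
#'
#' Constants of the isotropic neo-Hookean strain-energy function
#' \deqn{W = C_1 (I_1 - 3) + \frac{1}{D_1}(J-1)^2,} with `D1 = 0` interpreted
#' as the exact-incompressibility limit (volumetric term dropped, `J = 1`
#' enforced). The small-strain shear modulus is \eqn{\mu = 2 C_1} and the
#' incompressible Young's modulus \eqn{E = 6 C_1}.
#'
#' @param C1 Linear part of the elastic energy, Pa.
#' @param D1 Compressibility parameter, 1/Pa (`0` = exactly incompressible).
#' @param thickness_artery Arterial wall thickness, m.
#' @param thickness_sac Aneurysm sac wall thickness, m.
#' @return An object of class `wall_material`.
#' @export
wall_material <- function(C1 = 166e3, D1 = 0,
                          thickness_artery = 125e-6, thickness_sac = 27e-6) {
  if (!is.finite(C1) || C1 <= 0) stop("C1 must be > 0")
  if (!is.finite(D1) || D1 < 0) stop("D1 must be >= 0")
  if (thickness_artery <= 0 || thickness_sac <= 0) stop("thicknesses must be > 0")
  structure(list(C1 = C1, D1 = D1, thickness_artery = thickness_artery,
                 thickness_sac = thickness_sac),
            class = "wall_material")
}

#' @export
print.wall_material <- function(x, ...) {
  cat("Neo-Hookean wall material\n")
  cat(sprintf("  C1 = %g kPa  (mu = 2*C1 = %g kPa)\n", x$C1 / 1e3, 2 * x$C1 / 1e3))
  cat(sprintf("  D1 = %g 1/Pa %s\n", x$D1,
              if (x$D1 == 0) "(exactly incompressible)" else ""))
  cat(sprintf("  thickness: artery %g um, sac %g um\n",
              x$thickness_artery * 1e6, x$thickness_sac * 1e6))
  invisible(x)
}

#' Neo-Hookean strain-energy density
#'
#' @param I1 First invariant of the right Cauchy-Green tensor (>= 3 for
#'   isochoric deformations).
#' @param J Elastic volume ratio (> 0). Must equal 1 when `D1 = 0`.
#' @param mat A [wall_material()] object.
#' @return Energy density, J/m^3; zero in the undeformed state.
#' @export
strain_energy <- function(I1, J = 1, mat = wall_material()) {
  if (any(J <= 0)) stop("J must be > 0")
  if (mat$D1 == 0) {
    if (any(abs(J - 1) > 1e-12))
      stop("incompressible material (D1 = 0) requires J = 1")
    vol <- 0
  } else {
    vol <- (1 / mat$D1) * (J - 1)^2
  }
  mat$C1 * (I1 - 3) + vol
}

#' Uniaxial nominal stress of the incompressible neo-Hookean solid
#'
#' First Piola-Kirchhoff stress along the loading axis for an incompressible
#' uniaxial stretch \eqn{\lambda}: \eqn{\sigma_N = 2 C_1 (\lambda -
#' \lambda^{-2})}. Zero at \eqn{\lambda = 1}; its slope there, \eqn{6 C_1},
#' is the incompressible small-strain Young's modulus.
#'
#' @param lambda Stretch ratio(s) (> 0).
#' @param mat A [wall_material()] object.
#' @return Nominal stress, Pa.
#' @export
uniaxial_nominal_stress <- function(lambda, mat = wall_material()) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  2 * mat$C1 * (lambda - lambda^-2)
}

membrane_state <- function(lambda, R0, t0) {
  structure(list(stretch = lambda,
                 displacement = (lambda - 1) * R0,
                 hoop_stress = NA_real_,  # filled by callers
                 thickness = t0 / lambda),
            class = "membrane_state")
}

#' Thin-wall equilibrium of a pressurized cylindrical segment
#'
#' Axially tethered (plane-strain) incompressible neo-Hookean membrane tube of
#' reference radius `R0` and thickness `t0` under transmural pressure `P`.
#' Hoop Cauchy stress \eqn{\mu(\lambda^2 - \lambda^{-2})} (with
#' \eqn{\mu = 2C_1}) balances the Laplace law in the deformed configuration,
#' \deqn{\mu(\lambda^2 - \lambda^{-2}) = P\,\lambda^2 R_0 / t_0,}
#' which has the closed-form root \eqn{\lambda = (1 - P R_0/(\mu
#' t_0))^{-1/4}} on \eqn{P < \mu t_0 / R_0}. Beyond that pressure the tube has
#' no equilibrium (unbounded inflation) and an error is raised.
#'
#' @param transmural_pressure Pressure difference across the wall, Pa (>= 0).
#' @param R0 Reference (unloaded) radius, m.
#' @param t0 Reference wall thickness, m.
#' @param mat A [wall_material()] object.
#' @return A `membrane_state` list: `stretch`, `displacement` (m),
#'   `hoop_stress` (Cauchy, Pa), `thickness` (current, m).
#' @export
tube_equilibrium <- function(transmural_pressure, R0, t0, mat = wall_material()) {
  P <- transmural_pressure
  if (P < 0) stop("transmural pressure must be >= 0")
  if (R0 <= 0 || t0 <= 0) stop("R0 and t0 must be > 0")
  mu <- 2 * mat$C1
  Pcrit <- mu * t0 / R0
  if (P >= Pcrit)
    stop(sprintf(paste("loss of stability: P = %g Pa reaches the unbounded-",
                       "inflation limit mu*t0/R0 = %g Pa of the tube"),
                 P, Pcrit))
  lam <- (1 - P * R0 / (mu * t0))^(-1 / 4)
  st <- membrane_state(lam, R0, t0)
  st$hoop_stress <- mu * (lam^2 - lam^-2)
  st$residual <- mu * (lam^2 - lam^-2) - P * lam^2 * R0 / t0
  st
}

#' Thin-wall equilibrium of a pressurized spherical sac
#'
#' Classic incompressible neo-Hookean balloon relation for a sphere of
#' reference radius `R0` and thickness `t0`:
#' \deqn{P(\lambda) = 2\mu \frac{t_0}{R_0}\left(\lambda^{-1} -
#' \lambda^{-7}\right), \quad \mu = 2C_1.}
#' `P` rises to a limit point at \eqn{\lambda^* = 7^{1/6} \approx 1.3831}
#' and the ascending branch (\eqn{\lambda \le \lambda^*}) is returned; for
#' pressures above the limit-point pressure an error names the limit point.
#'
#' @inheritParams tube_equilibrium
#' @return A `membrane_state` list (see [tube_equilibrium()]); biaxial Cauchy
#'   stress in `hoop_stress`, current thickness \eqn{t_0/\lambda^2}.
#' @export
sphere_equilibrium <- function(transmural_pressure, R0, t0, mat = wall_material()) {
  P <- transmural_pressure
  if (P < 0) stop("transmural pressure must be >= 0")
  if (R0 <= 0 || t0 <= 0) stop("R0 and t0 must be > 0")
  mu <- 2 * mat$C1
  lam_star <- 7^(1 / 6)
  p_of_lam <- function(l) 2 * mu * (t0 / R0) * (l^-1 - l^-7)
  P_max <- p_of_lam(lam_star)
  if (P > P_max)
    stop(sprintf(paste("balloon limit point exceeded: P = %g Pa > P_max = %g Pa",
                       "(limit point at lambda = 7^(1/6) = %.4f)"),
                 P, P_max, lam_star))
  lam <- if (P == 0) 1 else
    stats::uniroot(function(l) p_of_lam(l) - P, c(1, lam_star),
                   tol = 1e-14)$root
  st <- membrane_state(lam, R0, t0)
  st$thickness <- t0 / lam^2
  st$hoop_stress <- mu * (lam^2 - lam^-4)
  st$residual <- p_of_lam(lam) - P
  st$P_max <- P_max
  st
}

# ---- hoop-foundation helpers (prestressed as-meshed configuration) --------
#
# The as-meshed wall is taken to be the equilibrium configuration under the
# reference transmural pressure P_pre. Inverting the tube relation with the
# *as-meshed* radius Rm and thickness tm gives the prestretch directly:
#   cylinder: mu (l^2 - l^-2) = P_pre * Rm / tm * l^2  =>  closed form below
#   sphere:   2 mu (tm/Rm) (l^2 - l^-4) = P_pre
# and the nonlinear restoring transmural pressure for a further normal
# displacement d (total stretch l = l_pre * (1 + d/Rm)) follows from the same
# relations written with the stress-free radius Rm/l_pre.

prestretch_cylinder <- function(P_pre, Rm, tm, mu) {
  if (P_pre <= 0) return(1)
  rhs <- P_pre * Rm / tm / mu          # = l^2 - l^-2 over l^2 -> 1 - l^-4
  if (rhs >= 1) stop("prestress pressure exceeds cylinder capacity")
  (1 - rhs)^(-1 / 4)
}

prestretch_sphere <- function(P_pre, Rm, tm, mu) {
  if (P_pre <= 0) return(1)
  f <- function(l) 2 * mu * (tm / Rm) * (l^2 - l^-4) - P_pre
  stats::uniroot(f, c(1, 50), tol = 1e-13)$root
}

# Restoring transmural pressure P(l) at total stretch l for a wall node whose
# as-meshed state (Rm, tm) is prestretched by l_pre. kind: 1 cylinder, 2 sphere.
foundation_pressure <- function(l, l_pre, Rm, tm, mu, kind) {
  Rsf <- Rm / l_pre
  out <- numeric(length(l))
  cyl <- kind == 1L
  if (any(cyl)) {                       # plane-strain cylinder, tsf = tm*l_pre
    tsf <- tm[cyl] * l_pre[cyl]
    out[cyl] <- mu * (l[cyl]^2 - l[cyl]^-2) * tsf / (l[cyl]^2 * Rsf[cyl])
  }
  if (any(!cyl)) {                      # equibiaxial sphere, tsf = tm*l_pre^2
    tsf <- tm[!cyl] * l_pre[!cyl]^2
    out[!cyl] <- 2 * mu * (tsf / Rsf[!cyl]) * (l[!cyl]^-1 - l[!cyl]^-7)
  }
  out
}

#' Nonlinear membrane update of the arterial wall curve
#'
#' Quasi-static equilibrium of the 2D wall curve under a per-node traction
#' load. The wall resists with (i) arc-length string tension from the
#' plane-strain neo-Hookean law applied to segment stretch on top of the
#' prestress tension, and (ii) a nonlinear hoop (Laplace) foundation per node
#' that represents the out-of-plane circumferential load path of the vessel,
#' linearizing to the thin-wall tube/sphere equilibria for uniform loads.
#' Anchor nodes (the inlet/outlet rings) are clamped. Solved by Newton
#' iteration on the free nodal positions with an analytic tangent.
#'
#' @param interface_curve A wall-interface description as built by
#'   [wall_interface()]: ordered chains of wall nodes with reference
#'   positions, outward normals, per-node thickness, local radius and
#'   prestress pressure.
#' @param traction N x 2 matrix of traction increments (Pa) at the wall nodes
#'   (relative to the prestressed datum), in global x-y components, positive
#'   pushing outward along the stored normals.
#' @param mat A [wall_material()] object.
#' @param anchors Integer indices (into the interface node list) of clamped
#'   nodes; defaults to the chain endpoints stored in the curve.
#' @param tol Relative residual tolerance (scaled by the load norm).
#' @param max_iters Newton iteration cap.
#' @return A list with `displacement` (N x 2, m), `normal_displacement`
#'   (signed, along the outward normal), and `residual_norm`.
#' @export
membrane_wall_update <- function(interface_curve, traction,
                                 mat = wall_material(),
                                 anchors = interface_curve$anchors,
                                 tol = 1e-8, max_iters = 60) {
  ic <- interface_curve
  X0 <- ic$nodes
  nn <- nrow(X0)
  if (is.null(dim(traction))) traction <- matrix(traction, ncol = 2)
  stopifnot(nrow(traction) == nn)
  if (length(anchors) == 0) stop("anchors must be nonempty (clamped rings)")
  mu <- 2 * mat$C1

  segs <- ic$segments                       # two-column node-index matrix
  a <- segs[, 1]; b <- segs[, 2]
  L0 <- sqrt(rowSums((X0[b, , drop = FALSE] - X0[a, , drop = FALSE])^2))
  t_seg <- 0.5 * (ic$thickness[a] + ic$thickness[b])
  # axial tether prestress tension (hoop-equivalent P_pre * R / 2)
  T0_seg <- 0.5 * (ic$pre_tension[a] + ic$pre_tension[b])

  # per-node lumped arc length (half of adjacent segments)
  wlen <- numeric(nn)
  wlen[a] <- wlen[a] + L0 / 2
  wlen[b] <- wlen[b] + L0 / 2

  free <- setdiff(seq_len(nn), sort(unique(anchors)))
  idx <- matrix(0L, nn, 2)
  idx[free, 1] <- seq_along(free) * 2L - 1L
  idx[free, 2] <- seq_along(free) * 2L
  ndof <- 2L * length(free)
  if (ndof == 0)
    return(list(displacement = matrix(0, nn, 2),
                normal_displacement = numeric(nn),
                residual_norm = 0, iterations = 0L))

  acc <- function(v, g) {                  # scatter-add v by group index g
    out <- numeric(nn)
    s <- rowsum(v, g)
    out[as.integer(rownames(s))] <- s
    out
  }

  load <- traction * wlen                  # line load, N/m
  res_scale <- max(sqrt(sum(load[free, ]^2)), 1e-12)
  # roundoff floor: segment tensions are mu*t*(lambda - lambda^-3) and the
  # stretch carries the relative rounding of the nodal coordinates, so very
  # stiff walls cannot equilibrate below this force noise
  lam_eps <- .Machine$double.eps * max(abs(X0)) / min(L0)
  res_floor <- 20 * mu * max(t_seg) * 4 * lam_eps * sqrt(nrow(segs))
  x <- X0
  res_norm <- Inf
  it <- 0L
  R_ref <- NULL   # reference-state internal force (self-equilibrated datum)

  for (it in seq_len(max_iters)) {
    d <- x - X0
    dn <- rowSums(d * ic$normals)          # outward-normal displacement
    lam_tot <- ic$prestretch * pmax(1 + dn / ic$local_radius, 1e-3)
    # hoop-foundation restoring pressure relative to the prestress datum
    p_found <- foundation_pressure(lam_tot, ic$prestretch, ic$local_radius,
                                   ic$thickness, mu, ic$kind) -
               ic$pre_pressure

    ev <- x[b, , drop = FALSE] - x[a, , drop = FALSE]
    L <- sqrt(rowSums(ev^2))
    tau <- ev / L
    lam_s <- L / L0                        # arc-length stretch (axial lam0 = 1)
    # plane-strain membrane Cauchy tension per unit depth, zero at lam_s = 1
    Tten <- T0_seg + t_seg * mu * (lam_s - lam_s^-3)
    dT_dlam <- t_seg * mu * (1 + 3 * lam_s^-4)

    Fa <- Tten * tau                       # force on node a (towards b)
    Rint <- -ic$normals * (p_found * wlen)
    for (k in 1:2)
      Rint[, k] <- Rint[, k] + acc(Fa[, k], a) - acc(Fa[, k], b)
    if (is.null(R_ref)) R_ref <- Rint      # as-meshed state is equilibrated:
    Rres <- load + Rint - R_ref            # only force increments act

    res_norm <- sqrt(sum(Rres[free, ]^2))
    if (res_norm < tol * res_scale + res_floor) break
    if (it == max_iters)
      stop(sprintf("membrane Newton did not converge: residual %.3e N/m",
                   res_norm))

    # tangent stiffness (sparse triplets); string material + geometric parts
    nseg <- length(a)
    ii <- integer(0); jj <- integer(0); vv <- numeric(0)
    add <- function(r, c, v) {
      keep <- r > 0L & c > 0L
      ii <<- c(ii, r[keep]); jj <<- c(jj, c[keep]); vv <<- c(vv, v[keep])
    }
    for (p in 1:2) for (q in 1:2) {
      kpq <- (dT_dlam / L0) * tau[, p] * tau[, q] +
        (Tten / L) * ((p == q) - tau[, p] * tau[, q])
      add(idx[a, p], idx[a, q],  kpq)
      add(idx[b, p], idx[b, q],  kpq)
      add(idx[a, p], idx[b, q], -kpq)
      add(idx[b, p], idx[a, q], -kpq)
    }
    # foundation: d(p_found)/d(dn) = dP/dl * l_pre / R_local
    dp_dl <- foundation_dPdl(lam_tot, ic$prestretch, ic$local_radius,
                             ic$thickness, mu, ic$kind)
    kf <- dp_dl * ic$prestretch / ic$local_radius * wlen
    for (p in 1:2) for (q in 1:2)
      add(idx[, p], idx[, q], kf * ic$normals[, p] * ic$normals[, q])

    K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ndof, ndof))
    rhs <- as.numeric(t(Rres[free, , drop = FALSE]))
    dx <- tryCatch(as.numeric(Matrix::solve(K, rhs)),
                   error = function(e)
                     stop(sprintf(
                       "membrane Newton diverged (singular tangent), residual %.3e",
                       res_norm)))
    step <- matrix(0, nn, 2)
    step[free, ] <- matrix(dx, ncol = 2, byrow = TRUE)
    mx <- max(abs(step))
    cap <- 0.2 * min(ic$local_radius)      # safeguard against overshoot
    if (mx > cap) step <- step * (cap / mx)
    x <- x + step
  }

  disp <- x - X0
  list(displacement = disp,
       normal_displacement = rowSums(disp * ic$normals),
       residual_norm = res_norm,
       iterations = it)
}

# derivative of foundation_pressure w.r.t. total stretch l
foundation_dPdl <- function(l, l_pre, Rm, tm, mu, kind) {
  Rsf <- Rm / l_pre
  out <- numeric(length(l))
  cyl <- kind == 1L
  if (any(cyl)) {
    tsf <- tm[cyl] * l_pre[cyl]
    out[cyl] <- mu * tsf / Rsf[cyl] * (4 * l[cyl]^-5)
  }
  if (any(!cyl)) {
    tsf <- tm[!cyl] * l_pre[!cyl]^2
    out[!cyl] <- 2 * mu * (tsf / Rsf[!cyl]) * (-l[!cyl]^-2 + 7 * l[!cyl]^-8)
  }
  out
}
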