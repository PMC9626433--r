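# Shared fixtures, memoised so expensive solves run once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

newtonian_blood <- function(mu = 0.004)
  rheology_params(kappa = mu, n = 1, tau0 = 0, gamma_min = 1e-6)

channel_fixture <- function()
  cached("channel", build_channel(length = 12e-3, width = 3.2e-3,
                                  mesh_size = 2.5e-4))

channel_newtonian_flow <- function()
  cached("channel_newt_flow",
         solve_steady_flow(channel_fixture(), newtonian_blood(), flow_bcs()))

channel_hb_flow <- function()
  cached("channel_hb_flow",
         solve_steady_flow(channel_fixture(), rheology_params(), flow_bcs()))

# long channel: lets the Herschel-Bulkley profile fully develop downstream
# of the (parabolic) inlet before comparing against the analytic oracle
long_channel_fixture <- function()
  cached("long_channel", build_channel(length = 40e-3, width = 3.2e-3,
                                       mesh_size = 2e-4))

long_channel_hb_flow <- function()
  cached("long_channel_hb_flow",
         solve_steady_flow(long_channel_fixture(), rheology_params(),
                           flow_bcs()))

intact_mesh <- function() cached("intact_mesh",
                                 build_scenario(scenario_spec("INTACT")))

intact_flow <- function()
  cached("intact_flow",
         solve_steady_flow(intact_mesh(), rheology_params(), flow_bcs()))

intact_wss <- function()
  cached("intact_wss",
         compute_wss(intact_flow(), intact_mesh(), rheology_params()))

# analytic plane-Poiseuille nodal field on a channel mesh (Newtonian)
poiseuille_field <- function(mesh, mu = 0.004, vmean = 0.23,
                             outlet_pressure = 4000) {
  h <- mesh$spec$parent_diameter
  L <- mesh$spec$parent_length
  G <- 12 * mu * vmean / h^2
  y <- mesh$nodes[, 2]
  u <- cbind((G / (2 * mu)) * ((h / 2)^2 - y^2), 0 * y)
  p <- G * (L - mesh$nodes[, 1])
  structure(list(velocity = u, pressure = p,
                 pressure_abs = p + outlet_pressure,
                 viscosity = rep(mu, nrow(mesh$nodes)),
                 residuals = numeric(0), converged = TRUE, stalled = FALSE,
                 reynolds = NA_real_, bcs = flow_bcs()),
            class = "flow_field")
}

# manual flow_field from a velocity matrix and constant pressure
manual_field <- function(mesh, velocity, pressure = 0, mu = 0.004) {
  n <- nrow(mesh$nodes)
  structure(list(velocity = velocity,
                 pressure = rep(pressure, n),
                 pressure_abs = rep(pressure, n),
                 viscosity = rep(mu, n),
                 residuals = numeric(0), converged = TRUE, stalled = FALSE,
                 reynolds = NA_real_, bcs = flow_bcs(outlet_pressure = 0)),
            class = "flow_field")
}

rotate_mesh <- function(mesh, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  out <- mesh
  out$nodes <- mesh$nodes %*% t(R)
  out$boundary_normal <- mesh$boundary_normal %*% t(R)
  for (nm in names(out$ports)) {
    out$ports[[nm]]$center <- as.numeric(R %*% mesh$ports[[nm]]$center)
    out$ports[[nm]]$normal <- as.numeric(R %*% mesh$ports[[nm]]$normal)
    out$ports[[nm]]$flow_dir <- as.numeric(R %*% mesh$ports[[nm]]$flow_dir)
  }
  out
}
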