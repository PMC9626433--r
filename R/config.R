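## YAML configuration loading and unit conversions.
##
## All internal computation is SI (m, s, Pa, kg/m^3). The config loader
## accepts bare numbers (already SI) or unit-tagged strings for pressures
## ("120 mmHg", "16 kPa", "4000 Pa") and viscosities ("0.04 g/(cm.s)",
## i.e. CGS poise notation, converted to Pa s).

MMHG_PA <- 133.322387415

#' Pressure unit conversions
#'
#' Exact conversion between mmHg and Pa (1 mmHg = 133.322387415 Pa), used by
#' the config loader so that clinically quoted pressures (e.g. 120 mmHg,
#' approximately 16 kPa) enter the model consistently.
#'
#' @param x Pressure value(s).
#' @return Converted value(s).
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

#' Parse a pressure config entry to Pa
#'
#' Numbers pass through as Pa; strings may carry a unit: `"Pa"`, `"kPa"`,
#' `"mmHg"`.
#'
#' @param x Number or string like `"120 mmHg"`.
#' @return Pressure in Pa.
#' @export
parse_pressure <- function(x) {
  if (is.numeric(x)) return(x)
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(Pa|kPa|mmHg)$", s))[[1]]
  if (length(m) != 3) stop(sprintf("cannot parse pressure '%s'", x))
  v <- as.numeric(m[2])
  switch(m[3], Pa = v, kPa = v * 1e3, mmHg = mmhg_to_pa(v))
}

#' Parse a viscosity config entry to Pa s
#'
#' Numbers pass through as Pa s; strings may carry `"Pa.s"` or the CGS
#' `"g/(cm.s)"` (poise; 1 g/(cm s) = 0.1 Pa s).
#'
#' @param x Number or string like `"0.04 g/(cm.s)"`.
#' @return Viscosity in Pa s.
#' @export
parse_viscosity <- function(x) {
  if (is.numeric(x)) return(x)
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(Pa\\.?s|g/\\(cm\\.?s\\))$", s))[[1]]
  if (length(m) != 3) stop(sprintf("cannot parse viscosity '%s'", x))
  v <- as.numeric(m[2])
  if (grepl("^g/", m[3])) v * 0.1 else v
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]]))
      modify_list(base[[nm]], new[[nm]]) else new[[nm]]
  }
  base
}

#' Default pipeline configuration
#'
#' The nested list mirroring the constructors' defaults; a YAML file needs to
#' state only what it overrides.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    scenario = list(scenarios = c("INTACT", "ICAS", "ACA"),
                    parent_diameter = 3.2e-3,
                    daughter_diameter = 2.0e-3,
                    bifurcation_half_angle = 50,
                    parent_length = 12e-3,
                    daughter_length = 10e-3,
                    sac_radius = 2.5e-3,
                    sac_neck_width = 2.2e-3,
                    mesh_size = 2.5e-4,
                    seed = 1L),
    rheology = list(kappa = 8.9721e-3, n = 0.8601, tau0 = 0.0175,
                    rho = 1020, mu_ref = "0.04 g/(cm.s)", gamma_min = 1e-3),
    wall = list(C1 = "166 kPa", D1 = 0,
                thickness_artery = 125e-6, thickness_sac = 27e-6,
                external_pressure = 0),
    bcs = list(inlet_mean_velocity = 0.23,
               outlet_pressure = "4 kPa",
               inlet_reference_pressure = "16 kPa"),
    solver = list(stabilization = 1, picard_max_iters = 50,
                  picard_tol = 1e-8, stagnation_tol = 1e-3,
                  ramp_duration = 0.1, ramp_steps = 50),
    coupling = list(max_outer_iters = 50, interface_tol = 1e-7,
                    relaxation = "aitken", initial_factor = 0.5,
                    prestress = TRUE),
    report = list(include_series = TRUE, figures = TRUE))
}

#' Load a pipeline configuration
#'
#' Reads a YAML file (or takes a list), overlays it on [default_config()],
#' parses unit-tagged entries, and returns ready-to-use parameter objects.
#'
#' @param path YAML file path, a list of overrides, or `NULL` for defaults.
#' @return A list with elements `raw` (the merged config), `rheology`,
#'   `wall`, `bcs`, `solver`, `coupling`, `scenario_specs` (named list of
#'   [scenario_spec()]s), `report`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    over <- if (is.character(path)) yaml::read_yaml(path) else path
    cfg <- modify_list(cfg, over)
  }
  rh <- cfg$rheology
  params <- rheology_params(kappa = rh$kappa, n = rh$n, tau0 = rh$tau0,
                            rho = rh$rho,
                            mu_ref = parse_viscosity(rh$mu_ref),
                            gamma_min = rh$gamma_min)
  wl <- cfg$wall
  mat <- wall_material(C1 = parse_pressure(wl$C1), D1 = wl$D1,
                       thickness_artery = wl$thickness_artery,
                       thickness_sac = wl$thickness_sac)
  bc <- cfg$bcs
  bcs <- flow_bcs(inlet_mean_velocity = bc$inlet_mean_velocity,
                  outlet_pressure = parse_pressure(bc$outlet_pressure),
                  inlet_reference_pressure =
                    parse_pressure(bc$inlet_reference_pressure) -
                    parse_pressure(wl$external_pressure))
  sv <- cfg$solver
  settings <- solver_settings(stabilization = sv$stabilization,
                              picard_max_iters = sv$picard_max_iters,
                              picard_tol = sv$picard_tol,
                              stagnation_tol = sv$stagnation_tol,
                              ramp_duration = sv$ramp_duration,
                              ramp_steps = sv$ramp_steps)
  cp <- cfg$coupling
  cset <- coupling_settings(max_outer_iters = cp$max_outer_iters,
                            interface_tol = cp$interface_tol,
                            relaxation = cp$relaxation,
                            initial_factor = cp$initial_factor,
                            prestress = cp$prestress)
  sc <- cfg$scenario
  specs <- lapply(sc$scenarios, function(s)
    scenario_spec(s,
                  parent_diameter = sc$parent_diameter,
                  daughter_diameter = sc$daughter_diameter,
                  bifurcation_half_angle = sc$bifurcation_half_angle,
                  parent_length = sc$parent_length,
                  daughter_length = sc$daughter_length,
                  sac_radius = sc$sac_radius,
                  sac_neck_width = sc$sac_neck_width,
                  mesh_size = sc$mesh_size,
                  seed = sc$seed))
  names(specs) <- sc$scenarios
  list(raw = cfg, rheology = params, wall = mat, bcs = bcs,
       solver = settings, coupling = cset,
       scenario_specs = specs, report = cfg$report)
}
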