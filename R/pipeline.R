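# End-to-end orchestration: geometry -> waveforms -> boundary conditions ->
# pulsatile solve -> TAWSS analytics -> case report, plus the paired
# pre/post virtual-angioplasty run.

#' Named solver profiles
#'
#' `"default"` is the production profile (mesh edge ~ 1/8 of the smallest
#' nominal radius, dt = T/1000, up to 6 cycles at 1% periodicity
#' tolerance); `"ci"` is a coarse profile for fast end-to-end runs (1/4
#' radius, dt = T/200, up to 3 cycles at 5%).
#'
#' @param name `"default"` or `"ci"`.
#' @export
solver_profile <- function(name = c("default", "ci")) {
  name <- match.arg(name)
  if (name == "default") {
    list(res_div = 8, dt_div = 1000L, cycles_max = 6L, periodicity_tol = 0.01)
  } else {
    list(res_div = 4, dt_div = 200L, cycles_max = 3L, periodicity_tol = 0.05)
  }
}

#' Control-like case configuration
#'
#' A lesion-free femoral bifurcation with triphasic inflow: the synthetic
#' analogue of a patent, anatomically normal post-treatment configuration.
#' Vessel calibers (CFA 4 mm, SFA 3 mm, DFA 2.5 mm half-widths) are
#' plausible femoral values chosen for the analogue, not patient
#' measurements.
#'
#' @param profile `"ci"` or `"default"` solver profile.
#' @param seed integer seed for waveform noise.
#' @export
fixture_control_config <- function(profile = "ci", seed = 1L) {
  list(
    name = "control",
    geometry = list(
      vessels = list(
        list(name = "CFA", radius = 4e-3, length = 0.04, angle = 0),
        list(name = "SFA", radius = 3e-3, length = 0.06, angle = 0.15),
        list(name = "DFA", radius = 2.5e-3, length = 0.04, angle = -0.6)),
      lesions = list()),
    waveforms = list(
      # PSVs chosen so the duplex-derived outlet mean flows are consistent
      # with the inlet mean flow (~60:40 SFA:DFA split), as duplex targets
      # for Windkessel tuning must be
      CFA = list(psv = 0.9, reverse_fraction = 0.3, phase = "triphasic"),
      SFA = list(psv = 0.95, reverse_fraction = 0.3, phase = "triphasic"),
      DFA = list(psv = 0.90, reverse_fraction = 0.3, phase = "triphasic")),
    T = 1.0, noise_sd = 0.0,
    fluid = list(rho = 1060, hematocrit = 0.43),
    windkessel = list(mode = "tune", mean_pressure_target = 13332, tolerance = 0.05),
    solver = c(solver_profile(profile),
               list(backflow_beta = 0.2, convection = TRUE)),
    thresholds = c(0.4, 0.15, 0.05),
    seed = as.integer(seed))
}

#' Occlusion-like case configuration
#'
#' A proximal-SFA edge stenosis (50% area) just upstream of an annotated
#' endograft, with monophasic (no reverse phase) inflow: the synthetic
#' analogue of the adverse configuration in which recirculation zones are
#' not washed out by backflow.
#'
#' @inheritParams fixture_control_config
#' @export
fixture_occlusion_config <- function(profile = "ci", seed = 1L) {
  cfg <- fixture_control_config(profile, seed)
  cfg$name <- "occlusion"
  cfg$geometry$lesions <- list(
    list(vessel = "SFA", center_s = 0.012, length = 0.012,
         kind = "stenosis", severity = 0.5))
  cfg$geometry$endograft <- list(vessel = "SFA", s_start = 0.015, s_end = 0.06)
  cfg$waveforms <- list(
    # dampened monophasic inflow and SFA, preserved triphasic DFA; PSVs
    # again mass-consistent (~51:49 SFA:DFA split)
    CFA = list(psv = 0.35, reverse_fraction = 0, phase = "monophasic"),
    SFA = list(psv = 0.32, reverse_fraction = 0, phase = "monophasic"),
    DFA = list(psv = 1.0, reverse_fraction = 0.25, phase = "triphasic"))
  cfg$fluid <- list(rho = 1060, hematocrit = 0.30)
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file following the fixture-config schema (see
#'   [fixture_control_config()] for the field layout).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_graftflow("format_error", sprintf("config file does not exist: %s", path))
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  assert_that(is.list(cfg$geometry), "validation_error", "config needs a geometry block")
  assert_that(is.list(cfg$waveforms) && length(cfg$waveforms) == 3L,
              "validation_error", "config needs waveform entries for all three sites")
  assert_that(is.numeric(cfg$thresholds) && all(cfg$thresholds > 0),
              "validation_error", "thresholds must be positive")
  for (w in cfg$waveforms) {
    if (!is.null(w$csv))
      assert_that(file.exists(w$csv), "validation_error",
                  sprintf("referenced waveform file missing: %s", w$csv))
  }
  invisible(cfg)
}

site_waveform <- function(cfg, site) {
  w <- cfg$waveforms[[site]]
  if (!is.null(w$csv)) return(read_waveform_csv(w$csv, site = site))
  synth_duplex_waveform(w$psv, w$reverse_fraction %||% 0, T = cfg$T %||% 1,
                        phase = w$phase %||% "triphasic",
                        noise_sd = cfg$noise_sd %||% 0,
                        seed = (cfg$seed %||% 1L) + match(site, names(cfg$waveforms)),
                        site = site)
}

config_digest <- function(cfg) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

# Shared set-up of a case: geometry, mesh, waveforms, inlet flow and outlet
# Windkessel models. Returned so an intervention run can reuse identical
# boundary conditions on an edited geometry.
pipeline_setup <- function(cfg) {
  validate_run_config(cfg)
  geom <- build_geometry(cfg$geometry)
  vs <- geom$vessels
  fluid <- do.call(fluid_properties, cfg$fluid %||% list())
  sv <- cfg$solver
  res <- min(vapply(vs, `[[`, 0, "nominal_radius")) / (sv$res_div %||% 8)
  msh <- mesh_bifurcation(geom, res)
  waves <- lapply(names(cfg$waveforms), function(s) site_waveform(cfg, s))
  names(waves) <- names(cfg$waveforms)
  inlet_name <- vs[[1L]]$name
  flows <- lapply(names(waves), function(s)
    flow_from_centerline(waves[[s]], vs[[s]]$nominal_radius, fluid))
  names(flows) <- names(waves)
  depth <- sv$depth %||% (pi * vs[[1L]]$nominal_radius / 2)
  T <- cfg$T %||% 1
  wk <- cfg$windkessel
  daughters <- vapply(vs[2:3], `[[`, "", "name")
  if (identical(wk$mode, "tune")) {
    targets <- lapply(daughters, function(v)
      tuning_target(v, flows[[v]], wk$mean_pressure_target %||% 13332,
                    wk$tolerance %||% 0.05))
    outlets <- tune_rcr(targets, flows[[inlet_name]], geom, fluid, depth,
                        P_ref = wk$P_ref %||% 0)
  } else {
    outlets <- lapply(wk$outlets, function(o)
      rcr_parameters(o$Rp, o$C, o$Rd, o$P_ref %||% 0))
  }
  scfg <- solver_config(dt = T / (sv$dt_div %||% 1000),
                        cycles_max = sv$cycles_max %||% 6L,
                        periodicity_tol = sv$periodicity_tol %||% 0.01,
                        fluid = fluid, depth = depth,
                        backflow_beta = sv$backflow_beta %||% 0.2,
                        convection = sv$convection %||% TRUE)
  list(cfg = cfg, geom = geom, mesh = msh, waves = waves, flows = flows,
       fluid = fluid, outlets = outlets, scfg = scfg,
       inlet = flows[[inlet_name]], resolution = res)
}

pipeline_solve <- function(setup, geom = NULL) {
  geom <- geom %||% setup$geom
  msh <- if (identical(geom, setup$geom)) setup$mesh
  else mesh_bifurcation(geom, setup$resolution)
  hist <- solve_pulsatile(msh, setup$inlet, setup$outlets, setup$scfg)
  rec <- wall_shear(hist, msh, setup$fluid$mu)
  map <- tawss(rec, geom$wall_segments)
  rep <- low_tawss_report(map, setup$cfg$thresholds %||% c(0.4, 0.15, 0.05))
  list(mesh = msh, history = hist, shear = rec, tawss = map, report = rep)
}

case_report <- function(setup, solved) {
  rcr <- lapply(setup$outlets, function(p)
    list(Rp = p$Rp, C = p$C, Rd = p$Rd, P_ref = p$P_ref))
  list(
    provenance = list(
      package = "graftflow",
      version = as.character(utils::packageVersion("graftflow")),
      config_digest = config_digest(setup$cfg),
      seed = setup$cfg$seed %||% 1L,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    case = setup$cfg$name %||% "case",
    windkessel = rcr,
    periodic_cycle = solved$history$periodic_cycle,
    mass_balance_residual = solved$history$mass_residual,
    mean_inflow_m3s = mean(solved$history$inlet_flow$Q),
    outlet_mean_flows_m3s = lapply(solved$history$outlet_flows, function(f) mean(f$Q)),
    segment_minima_pa = as.list(solved$tawss$segment_minima),
    global_min = solved$report$global_min,
    thresholds = solved$report$thresholds,
    overall_fractions = solved$report$overall,
    segment_fractions = solved$report$by_segment)
}

write_case_artifacts <- function(setup, solved, report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$windkessel, file.path(output_dir, "windkessel.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tawss_csv(solved$tawss, file.path(output_dir, "tawss.csv"))
  for (s in names(setup$waves))
    write_waveform_csv(setup$waves[[s]], file.path(output_dir, sprintf("waveform_%s.csv", s)))
  nt <- ncol(solved$history$ux)
  ks <- unique(pmin(seq(1L, nt, by = setup$scfg$store_stride), nt))
  for (k in ks) {
    write_vtk(solved$mesh, file.path(output_dir, sprintf("field_%04d.vtk", k)),
              point_data = list(velocity = cbind(solved$history$ux[, k],
                                                 solved$history$uy[, k]),
                                pressure = solved$history$pressure[, k]))
  }
  utils::write.csv(data.frame(t = solved$history$inlet_flow$t,
                              Q_in = solved$history$inlet_flow$Q),
                   file.path(output_dir, "inlet_flow.csv"), row.names = FALSE)
  for (nm in names(solved$history$outlet_flows)) {
    f <- solved$history$outlet_flows[[nm]]
    utils::write.csv(data.frame(t = f$t, Q = f$Q),
                     file.path(output_dir, sprintf("outlet_flow_%s.csv", nm)),
                     row.names = FALSE)
  }
  tw <- numeric(nrow(solved$mesh$nodes))
  tw[solved$tawss$map$node] <- solved$tawss$map$tawss
  write_vtk(solved$mesh, file.path(output_dir, "tawss_wall.vtk"),
            point_data = list(tawss = tw))
  invisible(output_dir)
}

#' Run one case end to end
#'
#' Builds the geometry and mesh, synthesizes (or reads) the duplex
#' waveforms, converts the inlet centerline velocity to volumetric flow via
#' the Womersley tube relation, derives outlet Windkessel parameters (fixed
#' or tuned against the daughter-vessel flows), runs the pulsatile solver
#' to cycle periodicity, and reduces the result to a TAWSS map with
#' low-shear threshold reporting. Deterministic given `cfg$seed`.
#'
#' @param cfg run configuration (see [fixture_control_config()] /
#'   [read_run_config()]).
#' @param output_dir optional directory for artifacts (report.json,
#'   tawss.csv, waveform CSVs, VTK field snapshots).
#' @return list of class `case_result`: `report` (JSON-serializable case
#'   report), `tawss`, `history`, `mesh`, `setup`.
#' @export
run_case <- function(cfg, output_dir = NULL) {
  setup <- pipeline_setup(cfg)
  solved <- pipeline_solve(setup)
  report <- case_report(setup, solved)
  if (!is.null(output_dir)) write_case_artifacts(setup, solved, report, output_dir)
  structure(list(report = report, tawss = solved$tawss, history = solved$history,
                 shear = solved$shear, mesh = solved$mesh, setup = setup),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<case_result> '%s': periodic at cycle %d, mass residual %.2e\n",
              r$case, r$periodic_cycle, r$mass_balance_residual))
  cat(sprintf("  global min TAWSS %.4g Pa in %s (%s wall, s = %.1f mm)\n",
              r$global_min$tawss, r$global_min$segment %||% "?",
              r$global_min$vessel, r$global_min$s * 1e3))
  invisible(x)
}

#' Paired pre/post virtual-angioplasty run
#'
#' Runs the case, applies [virtual_angioplasty()] over `s_interval` on
#' `vessel`, re-runs the solver on the edited geometry under identical
#' boundary conditions (same inlet flow and the same Windkessel
#' parameters), and reports the TAWSS deltas via
#' [compare_interventions()].
#'
#' @param cfg run configuration.
#' @param vessel vessel carrying the treated segment.
#' @param s_interval `c(s0, s1)` interval m to inflate to nominal caliber.
#' @param output_dir optional artifact directory (before/ and after/
#'   subdirectories).
#' @return list of class `intervention_result`: `before`, `after`
#'   (case_result-like), `delta` (comparison report).
#' @export
run_intervention <- function(cfg, vessel, s_interval, output_dir = NULL) {
  setup <- pipeline_setup(cfg)
  # validate the interval before any solve
  geom_after <- virtual_angioplasty(setup$geom, vessel, s_interval)
  solved_before <- pipeline_solve(setup)
  solved_after <- pipeline_solve(setup, geom = geom_after)
  delta <- compare_interventions(solved_before$tawss, solved_after$tawss,
                                 setup$cfg$thresholds %||% c(0.4, 0.15, 0.05))
  rep_b <- case_report(setup, solved_before)
  rep_a <- case_report(setup, solved_after)
  rep_a$case <- paste0(rep_a$case, "_post_angioplasty")
  if (!is.null(output_dir)) {
    write_case_artifacts(setup, solved_before, rep_b, file.path(output_dir, "before"))
    write_case_artifacts(setup, solved_after, rep_a, file.path(output_dir, "after"))
    jsonlite::write_json(delta, file.path(output_dir, "delta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(before = list(report = rep_b, tawss = solved_before$tawss,
                               history = solved_before$history),
                 after = list(report = rep_a, tawss = solved_after$tawss,
                              history = solved_after$history),
                 delta = delta, setup = setup),
            class = "intervention_result")
}

#' @export
print.intervention_result <- function(x, ...) {
  cat("<intervention_result>\n")
  print(x$delta$segments)
  invisible(x)
}
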