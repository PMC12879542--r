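#' Run configuration with validated defaults
#'
#' Builds the full configuration of a simulation run from a (possibly
#' nested) list of overrides. Defaults correspond to the reference
#' experiment: 43 g LGA per 1000 g water (saturation-equivalent loading),
#' linear cooling 70 to 20 degC at 0.6 K/min, 100 rpm label, Tai-Shei
#' power-law kinetics, a 40-bin geometric grid from 1 to 1000 um, and the
#' quadratic alpha-LGA solubility with the absolute-temperature
#' convention. Unknown keys anywhere in the list are rejected; ranges and
#' units are validated at load time. Boundary units are degC, um, K/min
#' and g per kg water (or g/L, taken as g per litre of water); internally
#' everything is SI.
#'
#' @param overrides nested list of fields to override.
#' @return A validated configuration list of class \code{run_config}.
#' @export
run_config <- function(overrides = list()) {
  defaults <- list(
    run_label = "Run 1",
    rpm = 100,
    mode = "wellmixed",
    T_sat_nominal = 70,
    onset_threshold = 0.01,
    S_threshold = 1.10,
    rho_s = 1540,
    schedule = list(T0 = 70, T_final = 20, cooling_rate = 0.6,
                    mode = "imposed_ramp", heat_flux = NULL,
                    wetted_area = NULL, thermal_mass = NULL),
    kinetics = list(preset = "tai_shei", kN = NULL, n = NULL, kG = NULL,
                    g = NULL, source = NULL),
    grid = list(d_min_um = 1, d_max_um = 1000, n_bins = 40),
    solubility = list(a0 = 0.08131, a1 = 0.000595783, a2 = 1.10258e-6,
                      temp_convention = "absolute_kelvin",
                      validity_window = c(10, 80)),
    basis = list(C0 = NULL, loading_g_per_kg_water = 43,
                 loading_g_per_L = NULL, mass_water = 1.0,
                 M_LGA = 147.13, M_water = 18.015, rho_solution = 1000,
                 solution_volume = NULL),
    solver = list(rtol = 1e-8, atol_n = 1e-12, atol_alpha = 1e-16,
                  dt_out = 10, t_end = NULL),
    network = list(preset = NULL, zone_volume_fractions = NULL,
                   exchange_flows = NULL, heat_weights = NULL,
                   circulation_flow = NULL, wall_heat_fraction = 0.6))
  cfg <- .merge_config(defaults, overrides, path = "config")
  .validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

# recursive merge rejecting unknown keys
.merge_config <- function(defaults, overrides, path) {
  if (!is.list(overrides))
    stop(sprintf("'%s' must be a list of fields", path))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(paste0(path, "$", unknown), collapse = ", ")))
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(overrides[[k]]) && k != "network") {
      defaults[[k]] <- .merge_config(defaults[[k]], overrides[[k]],
                                     paste0(path, "$", k))
    } else if (k == "network" && is.list(overrides[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], overrides[[k]],
                                     paste0(path, "$", k))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  s <- cfg$schedule
  if (!(is.numeric(s$cooling_rate) && s$cooling_rate > 0) &&
      s$mode == "imposed_ramp")
    stop("invalid configuration field 'schedule$cooling_rate': must be > 0")
  if (!(s$T0 > s$T_final))
    stop("invalid configuration field 'schedule$T0': must exceed T_final")
  g <- cfg$grid
  if (!(g$d_min_um > 0 && g$d_max_um > g$d_min_um))
    stop("invalid configuration field 'grid$d_min_um/d_max_um'")
  if (!(g$n_bins >= 2))
    stop("invalid configuration field 'grid$n_bins': must be >= 2")
  if (!(cfg$rho_s > 0))
    stop("invalid configuration field 'rho_s': must be > 0")
  if (!cfg$mode %in% c("wellmixed", "zonal"))
    stop("invalid configuration field 'mode': wellmixed or zonal")
  if (!is.null(cfg$kinetics$preset) &&
      !cfg$kinetics$preset %in% c("tai_shei", "penchev"))
    stop("invalid configuration field 'kinetics$preset'")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{read_run_config}: a validated \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg a \code{\link{run_config}}.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' Converts a validated \code{\link{run_config}} into the objects consumed
#' by \code{\link{simulate_batch}} / \code{\link{simulate_zonal}}.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return List with \code{schedule}, \code{kinetics}, \code{grid},
#'   \code{solubility}, \code{basis}, \code{control}, \code{rho_s} and
#'   (zonal mode) \code{network}.
#' @export
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  s <- cfg$schedule
  schedule <- process_schedule(s$T0, s$T_final, s$cooling_rate, s$mode,
                               s$heat_flux, s$wetted_area, s$thermal_mass)
  k <- cfg$kinetics
  kinetics <- if (!is.null(k$kN)) {
    kinetic_params(k$kN, k$n, k$kG, k$g,
                   source = if (is.null(k$source)) "config" else k$source)
  } else if (identical(k$preset, "penchev")) kinetics_penchev()
  else kinetics_tai_shei()
  grid <- build_grid(cfg$grid$d_min_um * 1e-6, cfg$grid$d_max_um * 1e-6,
                     cfg$grid$n_bins)
  so <- cfg$solubility
  solub <- solubility_model(so$a0, so$a1, so$a2, so$temp_convention,
                            so$validity_window)
  b <- cfg$basis
  C0 <- b$C0
  if (is.null(C0)) {
    loading <- if (!is.null(b$loading_g_per_L)) b$loading_g_per_L
               else b$loading_g_per_kg_water  # g/L read as g per litre water
    C0 <- mole_fraction_from_loading(loading, b$M_LGA, b$M_water)
  }
  basis <- solution_basis(C0, b$mass_water, b$M_LGA, b$M_water,
                          b$rho_solution, b$solution_volume)
  sv <- cfg$solver
  control <- solver_control(rtol = sv$rtol, atol_n = sv$atol_n,
                            atol_alpha = sv$atol_alpha, dt_out = sv$dt_out,
                            t_end = sv$t_end)
  out <- list(schedule = schedule, kinetics = kinetics, grid = grid,
              solubility = solub, basis = basis, control = control,
              rho_s = cfg$rho_s)
  if (cfg$mode == "zonal") {
    nw <- cfg$network
    out$network <- if (identical(nw$preset, "three_zone")) {
      if (is.null(nw$circulation_flow))
        stop("network preset 'three_zone' needs circulation_flow")
      three_zone_template(basis$solution_volume, nw$circulation_flow,
                          nw$wall_heat_fraction)
    } else {
      if (is.null(nw$zone_volume_fractions))
        stop("zonal mode needs network$zone_volume_fractions or a preset")
      vf <- as.numeric(nw$zone_volume_fractions)
      Q <- nw$exchange_flows
      if (!is.null(Q)) Q <- do.call(rbind, lapply(Q, as.numeric))
      zone_network(vf / sum(vf) * basis$solution_volume, Q,
                   nw$heat_weights)
    }
  }
  out
}

#' Table 3 style run presets
#'
#' The four simulated experimental runs: impeller speed and kinetic
#' parameter provenance. Nucleation parameters are common (Tai-Shei);
#' growth parameters come from Tai-Shei (runs 1, 3) or from the fitted
#' Penchev data (runs 2, 4). In well-mixed mode the impeller speed is a
#' label only: the lumped power laws carry no agitation dependence.
#'
#' @param run run number 1--4.
#' @return A \code{\link{run_config}}.
#' @export
run_preset <- function(run) {
  stopifnot(run %in% 1:4)
  presets <- list(
    list(run_label = "Run 1", rpm = 100, kinetics = list(preset = "tai_shei")),
    list(run_label = "Run 2", rpm = 100, kinetics = list(preset = "penchev")),
    list(run_label = "Run 3", rpm = 150, kinetics = list(preset = "tai_shei")),
    list(run_label = "Run 4", rpm = 150, kinetics = list(preset = "penchev")))
  run_config(presets[[run]])
}

#' Summary report of a batch trajectory
#'
#' Collects the headline process results: crystallization onset time and
#' temperature, metastable zone width, peak supersaturation and its time,
#' residual supersaturation and total solids fraction at the end of the
#' batch, time to approach equilibrium, final Sauter mean diameter and
#' final CSD mode.
#'
#' @param traj a \code{batch_trajectory}.
#' @param T_sat_nominal nominal saturation temperature for the MSZW (degC).
#' @param onset_threshold relative concentration drop defining onset.
#' @param S_threshold supersaturation level defining the approach to
#'   equilibrium.
#' @param rpm impeller speed label (optional, reported only).
#' @param wellmixed_note add the note that rpm does not enter the
#'   well-mixed physics.
#' @return A list of class \code{run_report}.
#' @export
run_report <- function(traj, T_sat_nominal = 70, onset_threshold = 0.01,
                       S_threshold = 1.10, rpm = NA,
                       wellmixed_note = TRUE) {
  stopifnot(inherits(traj, "batch_trajectory"))
  d <- traj$data
  n <- nrow(d)
  on <- detect_onset(traj, onset_threshold)
  pk <- peak_supersaturation(traj)
  fin_pop <- if (d$phi_T[n] > 0) final_population(traj) else NULL
  rep <- list(
    label = traj$label, rpm = rpm,
    onset = on,
    mszw = if (on$detected) T_sat_nominal - on$T_onset else NA_real_,
    t_peak_min = pk$t_peak / 60, S_peak = pk$S_peak,
    t_desup_min = desupersaturation_time(traj, S_threshold) / 60,
    S_residual = d$S[n], phi_T_final = d$phi_T[n],
    d32_final_um = if (!is.null(fin_pop))
      sauter_mean_diameter(fin_pop) * 1e6 else NA_real_,
    csd_mode_um = if (!is.null(fin_pop))
      csd_mode(volume_percent_csd(fin_pop)) else NA_real_,
    mass_balance_residual = mass_balance_audit(traj),
    note = if (wellmixed_note)
      paste("impeller speed (rpm) does not enter the well-mixed model;",
            "runs sharing kinetic parameters are physically identical")
    else NULL)
  class(rep) <- "run_report"
  rep
}

#' @rdname run_report
#' @param x a \code{run_report}.
#' @param ... unused.
#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Batch crystallization report (%s%s)\n", x$label,
              if (!is.na(x$rpm)) sprintf(", %g rpm", x$rpm) else ""))
  if (x$onset$detected)
    cat(sprintf("  onset:            t = %.1f min, T = %.1f degC\n",
                x$onset$t_onset / 60, x$onset$T_onset))
  else cat("  onset:            not detected\n")
  cat(sprintf("  MSZW:             %.1f K\n", x$mszw))
  cat(sprintf("  peak S:           %.3f at %.1f min\n", x$S_peak,
              x$t_peak_min))
  cat(sprintf("  S < threshold at: %.1f min\n", x$t_desup_min))
  cat(sprintf("  residual S:       %.3f\n", x$S_residual))
  cat(sprintf("  final phi_T:      %.4f\n", x$phi_T_final))
  cat(sprintf("  final d32:        %.1f um\n", x$d32_final_um))
  cat(sprintf("  final CSD mode:   %.1f um\n", x$csd_mode_um))
  cat(sprintf("  mass-balance res: %.2e\n", x$mass_balance_residual))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Run a simulation from a configuration file and write outputs
#'
#' Loads a YAML configuration, runs the well-mixed or zonal simulation,
#' and writes \code{trajectory.csv}, \code{final_csd.csv} and
#' \code{report.txt} into \code{out_dir} (zonal mode additionally writes
#' \code{zone<k>_trajectory.csv} per zone; the averaged trajectory uses
#' the well-mixed schema).
#'
#' @param config_path YAML configuration file.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress the printed report.
#' @return The \code{\link{run_report}}, invisibly.
#' @export
cli_simulate <- function(config_path, out_dir = ".", quiet = FALSE) {
  cfg <- read_run_config(config_path)
  obj <- config_objects(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (cfg$mode == "zonal") {
    zt <- simulate_zonal(obj$network, obj$schedule, obj$kinetics, obj$grid,
                         obj$solubility, obj$basis, rho_s = obj$rho_s,
                         control = obj$control)
    for (z in seq_along(zt$zones))
      write_trajectory_csv(zt$zones[[z]],
                           file.path(out_dir,
                                     sprintf("zone%d_trajectory.csv", z)))
    traj <- zt$averaged
    note <- FALSE
  } else {
    traj <- simulate_batch(obj$schedule, obj$kinetics, obj$grid,
                           obj$solubility, obj$basis, rho_s = obj$rho_s,
                           control = obj$control)
    note <- TRUE
  }
  write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
  if (traj$data$phi_T[nrow(traj$data)] > 0)
    write_csd_csv(volume_percent_csd(final_population(traj)),
                  file.path(out_dir, "final_csd.csv"))
  rep <- run_report(traj, T_sat_nominal = cfg$T_sat_nominal,
                    onset_threshold = cfg$onset_threshold,
                    S_threshold = cfg$S_threshold, rpm = cfg$rpm,
                    wellmixed_note = note)
  txt <- utils::capture.output(print(rep))
  writeLines(txt, file.path(out_dir, "report.txt"))
  if (!quiet) print(rep)
  invisible(rep)
}

#' Fit growth kinetics from a CSV of (sigma, G) data
#'
#' Reads a two-column growth dataset (\code{sigma,G_m_per_s}) and fits the
#' power law by log-log least squares.
#'
#' @param csv_path dataset path.
#' @param quiet suppress printing.
#' @return The \code{\link{fit_growth_power_law}} result, invisibly.
#' @export
cli_fit_growth <- function(csv_path, quiet = FALSE) {
  fit <- fit_growth_power_law(read_growth_dataset(csv_path))
  if (!quiet)
    cat(sprintf("kG = %.4g m/s (se %.2g)\ng  = %.4g (se %.2g)\n",
                fit$kG, fit$se_kG, fit$g, fit$se_g))
  invisible(fit)
}
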