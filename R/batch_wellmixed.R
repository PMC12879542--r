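#' Cooling schedule for a batch crystallization run
#'
#' Defines how the (volume-averaged) vessel temperature evolves. In
#' \code{imposed_ramp} mode the temperature falls linearly at
#' \code{cooling_rate} K/min from \code{T0} until \code{T_final} and then
#' holds. In \code{jacket_flux} mode the ramp rate is derived from a
#' constant jacket heat flux, \eqn{dT/dt = -q'' A / C_{th}}, which requires
#' the wetted area and lumped thermal mass of the vessel contents.
#'
#' @param T0 initial temperature (degC).
#' @param T_final final temperature (degC), \code{< T0}.
#' @param cooling_rate cooling rate (K/min), \code{> 0} (imposed_ramp mode).
#' @param mode \code{"imposed_ramp"} or \code{"jacket_flux"}.
#' @param heat_flux jacket heat flux (W/m^2), jacket_flux mode only.
#' @param wetted_area heat-transfer area (m^2), jacket_flux mode only.
#' @param thermal_mass lumped heat capacity of the contents (J/K),
#'   jacket_flux mode only.
#' @return An object of class \code{process_schedule}.
#' @export
process_schedule <- function(T0 = 70, T_final = 20, cooling_rate = 0.6,
                             mode = c("imposed_ramp", "jacket_flux"),
                             heat_flux = NULL, wetted_area = NULL,
                             thermal_mass = NULL) {
  mode <- match.arg(mode)
  if (!(T0 > T_final)) stop("T0 must exceed T_final")
  if (mode == "imposed_ramp") {
    if (!(cooling_rate > 0)) stop("cooling_rate must be > 0")
    rate_K_per_s <- cooling_rate / 60
  } else {
    if (is.null(heat_flux) || is.null(wetted_area) || is.null(thermal_mass))
      stop("jacket_flux mode needs heat_flux, wetted_area and thermal_mass")
    rate_K_per_s <- heat_flux * wetted_area / thermal_mass
    if (!(rate_K_per_s > 0)) stop("jacket_flux parameters imply no cooling")
    cooling_rate <- rate_K_per_s * 60
  }
  structure(
    list(T0 = T0, T_final = T_final, cooling_rate = cooling_rate,
         rate_K_per_s = rate_K_per_s, mode = mode,
         heat_flux = heat_flux, wetted_area = wetted_area,
         thermal_mass = thermal_mass,
         t_ramp = (T0 - T_final) / rate_K_per_s),
    class = "process_schedule")
}

#' @rdname process_schedule
#' @param schedule a \code{process_schedule}.
#' @param t time(s) in seconds since the start of cooling.
#' @return \code{schedule_temperature}: vessel temperature(s) in degC.
#' @export
schedule_temperature <- function(schedule, t) {
  pmax(schedule$T_final, schedule$T0 - schedule$rate_K_per_s * t)
}

# instantaneous imposed cooling rate (K/s, >= 0)
.schedule_rate <- function(schedule, t) {
  ifelse(t < schedule$t_ramp, schedule$rate_K_per_s, 0)
}

#' Solution basis: fixed water mass carrying the solute balance
#'
#' The lumped solute balance is written in moles of LGA on a fixed mass of
#' water. The mole fraction is \eqn{x = n_{LGA}/(n_{LGA} + n_w)}. The
#' solution volume is treated as constant (dilute slurry, at most a few
#' percent solids) and defaults to total solution mass over
#' \code{rho_solution}.
#'
#' @param C0 initial solute mole fraction; default corresponds to the
#'   reference loading of 43 g LGA per 1000 g water.
#' @param mass_water basis water mass (kg).
#' @param M_LGA,M_water molar masses (g/mol).
#' @param rho_solution solution density (kg/m^3) used for the default
#'   volume.
#' @param solution_volume override the solution volume (m^3).
#' @return An object of class \code{solution_basis}.
#' @export
solution_basis <- function(C0 = mole_fraction_from_loading(43),
                           mass_water = 1.0, M_LGA = 147.13,
                           M_water = 18.015, rho_solution = 1000,
                           solution_volume = NULL) {
  stopifnot(C0 >= 0, C0 < 1, mass_water > 0)
  n_w <- 1000 * mass_water / M_water
  n_L0 <- C0 / (1 - C0) * n_w
  mass_solution <- mass_water + n_L0 * M_LGA / 1000
  if (is.null(solution_volume))
    solution_volume <- mass_solution / rho_solution
  structure(
    list(C0 = C0, mass_water = mass_water, M_LGA = M_LGA,
         M_water = M_water, n_water = n_w, n_LGA0 = n_L0,
         solution_volume = solution_volume),
    class = "solution_basis")
}

#' Solute mole fraction from a mass loading
#'
#' Converts grams of LGA per kilogram of water into a solute mole fraction
#' (mol LGA / mol solution). The reference loading of 43 g/kg gives
#' 0.0052374.
#'
#' @param g_per_kg_water solute loading (g solute per 1000 g water).
#' @param M_LGA,M_water molar masses (g/mol).
#' @export
mole_fraction_from_loading <- function(g_per_kg_water, M_LGA = 147.13,
                                       M_water = 18.015) {
  n_L <- g_per_kg_water / M_LGA
  n_w <- 1000 / M_water
  n_L / (n_L + n_w)
}

#' Solver and output controls for the batch / zonal integrators
#'
#' @param rtol relative tolerance of the stiff ODE solver.
#' @param atol_n absolute tolerance on the solute-mole state (mol).
#' @param atol_alpha absolute tolerance per crystal-volume-fraction bin.
#' @param dt_out output sampling interval (s).
#' @param t_end end time (s); defaults to the end of the cooling ramp.
#' @param hold_sigma if non-NULL, the relative supersaturation is clamped
#'   to this value (kinetics decoupled from the mass balance; used for
#'   verification against quadrature oracles).
#' @param method deSolve integration method.
#' @return A list of controls for \code{\link{simulate_batch}} and
#'   \code{\link{simulate_zonal}}.
#' @export
solver_control <- function(rtol = 1e-8, atol_n = 1e-12, atol_alpha = 1e-16,
                           dt_out = 10, t_end = NULL, hold_sigma = NULL,
                           method = "lsoda") {
  list(rtol = rtol, atol_n = atol_n, atol_alpha = atol_alpha,
       dt_out = dt_out, t_end = t_end, hold_sigma = hold_sigma,
       method = method)
}

# solubility evaluation without the validity-window warning (inner loops)
.cstar_quiet <- function(T, model) {
  Tp <- .temp_transform(T, model)
  model$a0 - model$a1 * Tp + model$a2 * Tp^2
}

# Shared network integrator. A well-mixed batch is the single-zone case.
# net: list(n_zones, V (m^3, sums to basis$solution_volume), Q, w)
# seed_alpha: n_zones x n_bins matrix of initial volume fractions
.integrate_network <- function(net, schedule, kinetics, grid, solub, basis,
                               rho_s, seed_alpha, control) {
  nz <- net$n_zones
  nb <- grid$n_bins
  V <- net$V
  Vtot <- sum(V)
  Q <- net$Q
  w <- net$w
  diag(Q) <- 0
  Qout <- rowSums(Q)          # total flow leaving each zone
  has_flow <- any(Q > 0)
  M_kg <- basis$M_LGA / 1000
  n_w_z <- basis$n_water * V / Vtot
  nL0_z <- basis$C0 / (1 - basis$C0) * n_w_z

  # temperature is algebraic (uniform) when heat removal is split in
  # proportion to zone volume; otherwise it is integrated per zone
  uniform_T <- max(abs(w - V / Vtot)) < 1e-12
  t_end <- if (is.null(control$t_end)) schedule$t_ramp else control$t_end
  times <- unique(c(seq(0, t_end, by = control$dt_out), t_end))

  y0 <- c(nL0_z, as.vector(t(seed_alpha)))
  if (!uniform_T) y0 <- c(y0, rep(schedule$T0, nz))
  iT <- if (!uniform_T) length(y0) - nz + seq_len(nz) else NULL

  hold <- control$hold_sigma
  rhs <- function(t, y, p) {
    nL <- y[seq_len(nz)]
    Tz <- if (uniform_T) rep(schedule_temperature(schedule, t), nz)
          else y[iT]
    dy <- numeric(length(y))
    al <- matrix(y[(nz + 1):(nz + nz * nb)], nrow = nz, byrow = TRUE)
    x <- nL / (nL + n_w_z)
    cs <- .cstar_quiet(Tz, solub)
    sig <- if (is.null(hold)) x / cs - 1 else rep(hold, nz)
    G <- growth_rate_linear(sig, kinetics)
    nd <- nucleation_rate(sig, kinetics)
    dal <- matrix(0, nz, nb)
    dnL <- numeric(nz)
    for (z in seq_len(nz)) {
      da <- .growth_rates_raw(al[z, ], grid, G[z])
      da[1] <- da[1] + grid$V0 * nd[z]
      dal[z, ] <- da
      dnL[z] <- -(rho_s * V[z] / M_kg) * sum(da)
    }
    if (has_flow) {
      # convective exchange at donor composition: moles move as Q * c_donor,
      # crystal volume as Q * alpha_donor (then scaled by receiver volume)
      conc <- nL / V
      dnL <- dnL + as.vector(crossprod(Q, conc)) - Qout * conc
      dal <- dal + (crossprod(Q, al) - Qout * al) / V
    }
    dy[seq_len(nz)] <- dnL
    dy[(nz + 1):(nz + nz * nb)] <- as.vector(t(dal))
    if (!uniform_T) {
      r <- .schedule_rate(schedule, t)
      dT <- -r * w * Vtot / V
      if (has_flow)
        dT <- dT + (as.vector(crossprod(Q, Tz)) - Qout * Tz) / V
      dy[iT] <- dT
    }
    list(dy)
  }

  atol <- c(rep(control$atol_n, nz), rep(control$atol_alpha, nz * nb))
  if (!uniform_T) atol <- c(atol, rep(1e-8, nz))
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = control$method, rtol = control$rtol,
                      atol = atol)
  if (nrow(out) < length(times)) {
    last <- out[nrow(out), ]
    stop(sprintf(
      "ODE solver failed at t = %.3f s (last state: nL[1] = %.6g)",
      last[1], last[2]))
  }
  list(out = out, times = times, nz = nz, nb = nb, V = V, Vtot = Vtot,
       n_w_z = n_w_z, uniform_T = uniform_T, iT = iT)
}

# assemble a batch_trajectory from one zone's (or averaged) time series
.make_trajectory <- function(times, Tvec, nL, n_w, alpha, grid, schedule,
                             kinetics, solub, basis, rho_s, control,
                             label = "well-mixed") {
  x <- nL / (nL + n_w)
  if (any(x < -1e-12))
    stop("negative solute concentration: mass-balance failure")
  x <- pmax(x, 0)
  alpha <- pmax(alpha, 0)
  cs <- .cstar_quiet(Tvec, solub)
  S <- x / cs
  sig <- S - 1
  phi <- rowSums(alpha)
  d32 <- vapply(seq_along(times), function(i) {
    if (phi[i] <= 0) return(NA_real_)
    Ni <- alpha[i, ] / grid$Vi
    sum(Ni * grid$di^3) / sum(Ni * grid$di^2)
  }, numeric(1))
  eff_sig <- if (is.null(control$hold_sigma)) sig
             else rep(control$hold_sigma, length(sig))
  traj <- structure(
    list(data = data.frame(
           time = times, T = Tvec, C = x, Cstar = cs, S = S, sigma = sig,
           phi_T = phi, d32 = d32,
           ndot0 = nucleation_rate(eff_sig, kinetics),
           G = growth_rate_linear(eff_sig, kinetics)),
         alpha = alpha, grid = grid, schedule = schedule,
         kinetics = kinetics, solubility = solub, basis = basis,
         rho_s = rho_s, n_water = n_w, control = control, label = label),
    class = "batch_trajectory")
  traj
}

#' Simulate a well-mixed batch cooling crystallization
#'
#' Integrates the discrete-method population balance (growth and primary
#' nucleation power laws) coupled to a lumped solute mole balance and the
#' cooling schedule, from a crystal-free or seeded initial state. The solid
#' produced, \eqn{d\phi_T/dt = \sum_i d\alpha_i/dt}, is withdrawn from
#' solution as
#' \eqn{dn_{LGA}/dt = -(\rho_s V_{sol}/M_{LGA})\, d\phi_T/dt}.
#'
#' Construction fails if the solubility polynomial is non-positive anywhere
#' on the schedule's temperature range.
#'
#' @param schedule a \code{\link{process_schedule}}.
#' @param kinetics a \code{\link{kinetic_params}}.
#' @param grid a \code{\link{build_grid}} result.
#' @param solub a \code{\link{solubility_model}}.
#' @param basis a \code{\link{solution_basis}}.
#' @param seed_population optional \code{\link{crystal_population}} of
#'   seeds (NULL = unseeded).
#' @param rho_s crystal density (kg/m^3).
#' @param control a \code{\link{solver_control}} list.
#' @return A \code{batch_trajectory}: \code{$data} is a data.frame with
#'   columns time (s), T (degC), C (mole fraction), Cstar, S, sigma,
#'   phi_T, d32 (m), ndot0, G; \code{$alpha} the per-bin volume-fraction
#'   matrix (time x bin).
#' @export
simulate_batch <- function(schedule, kinetics, grid,
                           solub = solubility_model(),
                           basis = solution_basis(),
                           seed_population = NULL, rho_s = 1540,
                           control = solver_control()) {
  stopifnot(inherits(schedule, "process_schedule"),
            inherits(kinetics, "kinetic_params"),
            inherits(grid, "volume_grid"),
            inherits(basis, "solution_basis"))
  .check_solubility_positive(solub, schedule)
  seed <- matrix(0, 1, grid$n_bins)
  if (!is.null(seed_population)) {
    stopifnot(inherits(seed_population, "crystal_population"))
    seed[1, ] <- seed_population$alpha_i
  }
  net <- list(n_zones = 1L, V = basis$solution_volume,
              Q = matrix(0, 1, 1), w = 1)
  res <- .integrate_network(net, schedule, kinetics, grid, solub, basis,
                            rho_s, seed, control)
  nL <- res$out[, 2]
  alpha <- res$out[, 2 + seq_len(grid$n_bins), drop = FALSE]
  traj <- .make_trajectory(res$times,
                           schedule_temperature(schedule, res$times),
                           nL, basis$n_water, alpha, grid, schedule,
                           kinetics, solub, basis, rho_s, control)
  fin <- traj$data$phi_T[nrow(traj$data)]
  if (fin > 0 && traj$alpha[nrow(traj$alpha), grid$n_bins] > 0.01 * fin)
    warning("top size bin holds > 1% of final crystal volume: grid truncation risk")
  traj
}

.check_solubility_positive <- function(solub, schedule) {
  Ts <- seq(schedule$T_final, schedule$T0, length.out = 201)
  cs <- .cstar_quiet(Ts, solub)
  if (any(cs <= 0))
    stop(sprintf(
      "solubility model is non-positive at T = %g degC: cannot simulate",
      Ts[cs <= 0][1]))
  invisible(TRUE)
}

#' Solute/crystal mass-balance audit of a trajectory
#'
#' Relative residual of the lumped mass balance:
#' \deqn{\frac{|\Delta n_{LGA} + \rho_s V_{sol} \Delta\phi_T / M_{LGA}|}
#'   {n_{LGA}(0)}}
#' On a correct simulation this is bounded by the integrator tolerance
#' (well below 1e-6).
#'
#' @param traj a \code{batch_trajectory}.
#' @return The relative residual (dimensionless).
#' @export
mass_balance_audit <- function(traj) {
  stopifnot(inherits(traj, "batch_trajectory"))
  d <- traj$data
  n <- nrow(d)
  nL <- d$C / (1 - d$C) * traj$n_water
  M_kg <- traj$basis$M_LGA / 1000
  Vsol <- traj$basis$solution_volume
  abs((nL[n] - nL[1]) +
        traj$rho_s * Vsol * (d$phi_T[n] - d$phi_T[1]) / M_kg) / nL[1]
}

#' Detect the onset of crystallization from the concentration trace
#'
#' The onset is the first time at which the solute concentration has
#' fallen by \code{threshold} (relative) below its initial value, linearly
#' interpolated between samples. With \code{threshold = 0} the first
#' strictly decreasing sample is returned.
#'
#' @param traj a \code{batch_trajectory}.
#' @param threshold relative concentration drop defining onset
#'   (default 0.01, i.e. 1\%).
#' @return A list with \code{detected}, \code{t_onset} (s) and
#'   \code{T_onset} (degC); the latter two are \code{NA} when no onset is
#'   found.
#' @export
detect_onset <- function(traj, threshold = 0.01) {
  stopifnot(inherits(traj, "batch_trajectory"), threshold >= 0)
  d <- traj$data
  if (threshold == 0) {
    i <- which(diff(d$C) < 0)
    if (!length(i))
      return(list(detected = FALSE, t_onset = NA_real_, T_onset = NA_real_))
    t0 <- d$time[i[1] + 1]
    return(list(detected = TRUE, t_onset = t0,
                T_onset = schedule_temperature(traj$schedule, t0)))
  }
  target <- (1 - threshold) * d$C[1]
  i <- which(d$C < target)
  if (!length(i))
    return(list(detected = FALSE, t_onset = NA_real_, T_onset = NA_real_))
  i <- i[1]
  t0 <- if (i == 1) d$time[1] else {
    frac <- (d$C[i - 1] - target) / (d$C[i - 1] - d$C[i])
    d$time[i - 1] + frac * (d$time[i] - d$time[i - 1])
  }
  list(detected = TRUE, t_onset = t0,
       T_onset = schedule_temperature(traj$schedule, t0))
}

#' Metastable zone width
#'
#' The difference between a nominal saturation temperature and the
#' detected onset temperature on cooling.
#'
#' @param traj a \code{batch_trajectory}.
#' @param T_sat_nominal nominal saturation temperature (degC).
#' @param threshold onset threshold passed to \code{\link{detect_onset}}.
#' @return MSZW in kelvin (equivalently degC difference).
#' @export
mszw <- function(traj, T_sat_nominal, threshold = 0.01) {
  on <- detect_onset(traj, threshold)
  if (!on$detected) stop("no crystallization onset detected")
  T_sat_nominal - on$T_onset
}

#' Peak supersaturation of a trajectory
#'
#' Locates the maximum of the supersaturation ratio S over time. For an
#' interior maximum the peak is refined by parabolic interpolation through
#' the peak sample and its neighbours; a maximum at either endpoint is
#' returned as sampled.
#'
#' @param traj a \code{batch_trajectory}.
#' @return A list with \code{t_peak} (s) and \code{S_peak}.
#' @export
peak_supersaturation <- function(traj) {
  stopifnot(inherits(traj, "batch_trajectory"))
  d <- traj$data
  i <- which.max(d$S)
  n <- nrow(d)
  if (i == 1 || i == n)
    return(list(t_peak = d$time[i], S_peak = d$S[i]))
  t3 <- d$time[(i - 1):(i + 1)]
  s3 <- d$S[(i - 1):(i + 1)]
  denom <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
  a <- ((t3[3] - t3[2]) * s3[1] + (t3[1] - t3[3]) * s3[2] +
          (t3[2] - t3[1]) * s3[3]) / denom
  if (!is.finite(a) || a >= 0)
    return(list(t_peak = d$time[i], S_peak = d$S[i]))
  b <- ((t3[2]^2 - t3[3]^2) * s3[1] + (t3[3]^2 - t3[1]^2) * s3[2] +
          (t3[1]^2 - t3[2]^2) * s3[3]) / denom
  tp <- -b / (2 * a)
  c0 <- s3[2] - a * t3[2]^2 - b * t3[2]
  list(t_peak = tp, S_peak = a * tp^2 + b * tp + c0)
}

#' Time to approach equilibrium (desupersaturation time)
#'
#' First time after the supersaturation peak at which S falls below
#' \code{S_threshold}, linearly interpolated. (The solution starts
#' undersaturated, so the crossing is sought on the decaying branch after
#' the peak.)
#'
#' @param traj a \code{batch_trajectory}.
#' @param S_threshold supersaturation-ratio threshold (e.g. 1.10).
#' @return Time in seconds, or \code{NA} if S never falls below the
#'   threshold after its peak.
#' @export
desupersaturation_time <- function(traj, S_threshold) {
  stopifnot(inherits(traj, "batch_trajectory"))
  d <- traj$data
  ip <- which.max(d$S)
  idx <- which(d$S < S_threshold & seq_len(nrow(d)) > ip)
  if (!length(idx)) return(NA_real_)
  j <- idx[1]
  frac <- (d$S[j - 1] - S_threshold) / (d$S[j - 1] - d$S[j])
  d$time[j - 1] + frac * (d$time[j] - d$time[j - 1])
}

#' Write a batch trajectory as CSV
#'
#' One row per output time; scalar state columns followed by the per-bin
#' volume fractions \code{alpha_0 ... alpha_<n-1>}.
#'
#' @param traj a \code{batch_trajectory}.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  a <- as.data.frame(traj$alpha)
  names(a) <- paste0("alpha_", seq_len(ncol(a)) - 1L)
  utils::write.csv(cbind(traj$data, a), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Final crystal population of a trajectory
#'
#' @param traj a \code{batch_trajectory}.
#' @return The \code{\link{crystal_population}} at the last output time.
#' @export
final_population <- function(traj) {
  stopifnot(inherits(traj, "batch_trajectory"))
  crystal_population(traj$alpha[nrow(traj$alpha), ], traj$grid,
                     rho_s = traj$rho_s)
}
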