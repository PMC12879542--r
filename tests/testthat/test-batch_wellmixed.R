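test_that("a saturated solution with no cooling is a fixed point", {
  cfg <- fixture_equilibrium_case(T0 = 45)
  obj <- config_objects(cfg)
  traj <- simulate_batch(obj$schedule, obj$kinetics, obj$grid,
                         obj$solubility, obj$basis, control = obj$control)
  expect_equal(traj$data$C, rep(traj$data$C[1], nrow(traj$data)),
               tolerance = 1e-12)
  expect_lt(max(traj$data$phi_T), 1e-18)
  expect_equal(traj$data$S, rep(1, nrow(traj$data)), tolerance = 1e-9)
  expect_lt(mass_balance_audit(traj), 1e-12)
  on <- detect_onset(traj)
  expect_false(on$detected)
  expect_error(mszw(traj, 45), "no crystallization onset")
})

test_that("with kinetics disabled the trajectory follows the pure-cooling closed form", {
  off <- kinetic_params(kN = 0, n = 1, kG = 0, g = 1, source = "disabled")
  traj <- simulate_batch(ref_schedule(), off, ref_grid())
  m <- solubility_model()
  S_closed <- traj$data$C[1] / solubility(traj$data$T, m)
  expect_equal(traj$data$S, S_closed, tolerance = 1e-10)
  expect_true(all(traj$data$phi_T == 0))
})

test_that("deposited solid volume matches an independent quadrature oracle at held supersaturation", {
  grid <- ref_grid()
  seeds <- crystal_population(1e10 * ifelse(seq_len(40) ==
                                which.min(abs(grid$di - 50e-6)),
                              grid$Vi, 0), grid)
  no_nuc <- kinetic_params(kN = 0, n = 1, kG = 9.76e-8, g = 2.34,
                           source = "growth only")
  traj <- simulate_batch(ref_schedule(), no_nuc, grid,
                         seed_population = seeds,
                         control = solver_control(hold_sigma = 0.3,
                                                  dt_out = 5,
                                                  t_end = 1000))
  G <- growth_rate_linear(0.3, no_nuc)
  # oracle: phi gain = integral of sum_i N_i G_{v,i} dt on the stored samples
  integrand <- apply(traj$alpha, 1, function(a) {
    Ni <- a / grid$Vi
    sum(3 * grid$Vi / grid$di * G * Ni)
  })
  gain_oracle <- trapz(traj$data$time, integrand)
  gain <- traj$data$phi_T[nrow(traj$data)] - traj$data$phi_T[1]
  expect_lt(abs(gain - gain_oracle) / gain_oracle, 0.01)
})

test_that("the reference batch shows a single supersaturation maximum", {
  traj <- ref_batch()
  S <- traj$data$S
  ip <- which.max(S)
  expect_gt(ip, 1)
  expect_lt(ip, length(S))
  # exactly one sign change of dS/dt: rising branch then falling branch
  expect_true(all(diff(S[1:ip]) > 0))
  expect_true(all(diff(S[ip:length(S)]) < 0))
  pk <- peak_supersaturation(traj)
  expect_gte(pk$S_peak, max(S))
  expect_lt(abs(pk$t_peak - traj$data$time[ip]), traj$control$dt_out)
})

test_that("solute and crystal mass are conserved on every simulation", {
  expect_lt(mass_balance_audit(ref_batch()), 1e-6)
  seeded <- simulate_batch(ref_schedule(), kinetics_tai_shei(), ref_grid(),
                           seed_population = fixture_seeded_population(
                             ref_grid(), 50e-6, 0.3, 1e-4))
  expect_lt(mass_balance_audit(seeded), 1e-6)
  # a tampered trajectory reports a non-zero residual honestly
  bad <- ref_batch()
  bad$data$phi_T[nrow(bad$data)] <- bad$data$phi_T[nrow(bad$data)] * 1.05
  expect_gt(mass_balance_audit(bad), 1e-6)
})

test_that("total solids fraction never decreases in the growth/nucleation-only model", {
  traj <- ref_batch()
  expect_true(all(diff(traj$data$phi_T) >= -1e-15))
})

test_that("onset detection interpolates the threshold crossing and handles limits", {
  traj <- ref_batch()
  on <- detect_onset(traj, 0.01)
  expect_true(on$detected)
  # C at the interpolated time brackets the 1% target
  d <- traj$data
  i <- findInterval(on$t_onset, d$time)
  expect_true(d$C[i] >= 0.99 * d$C[1] && d$C[i + 1] <= 0.99 * d$C[1])
  expect_equal(on$T_onset,
               schedule_temperature(traj$schedule, on$t_onset))
  # threshold 0: first strictly decreasing sample, which is never later
  on0 <- detect_onset(traj, 0)
  expect_true(on0$detected)
  expect_lte(on0$t_onset, on$t_onset)
})

test_that("metastable zone width is monotone in the onset threshold", {
  traj <- ref_batch()
  w1 <- mszw(traj, 70, threshold = 0.005)
  w2 <- mszw(traj, 70, threshold = 0.01)
  w3 <- mszw(traj, 70, threshold = 0.02)
  expect_true(w1 <= w2 && w2 <= w3)
  expect_equal(mszw(traj, 70 , threshold = 0.01) -
                 mszw(traj, 60, threshold = 0.01), 10)
})

test_that("desupersaturation time is the first crossing after the peak", {
  traj <- ref_batch(t_end = 20000)
  t90 <- desupersaturation_time(traj, 1.10)
  d <- traj$data
  ip <- which.max(d$S)
  expect_gt(t90, d$time[ip])
  j <- findInterval(t90, d$time)
  expect_true(d$S[j] >= 1.10 && d$S[j + 1] <= 1.10)
  # a threshold never reached returns NA
  expect_true(is.na(desupersaturation_time(ref_batch(), 1.0)))
  # monotone-S run (kinetics off): peak at the final endpoint
  off <- kinetic_params(0, 1, 0, 1)
  toff <- simulate_batch(ref_schedule(), off, ref_grid())
  pk <- peak_supersaturation(toff)
  expect_equal(pk$t_peak, toff$data$time[nrow(toff$data)])
})

test_that("jacket-flux cooling reduces to the equivalent imposed ramp", {
  ramp <- process_schedule(70, 20, 0.6)
  # flux, area and thermal mass chosen to give the same 0.6 K/min
  jack <- process_schedule(70, 20, mode = "jacket_flux", heat_flux = 2499,
                           wetted_area = 0.25,
                           thermal_mass = 2499 * 0.25 / 0.01)
  expect_equal(jack$cooling_rate, 0.6)
  ts <- seq(0, 6000, by = 100)
  expect_equal(schedule_temperature(jack, ts), schedule_temperature(ramp, ts))
  expect_error(process_schedule(70, 20, mode = "jacket_flux"),
               "jacket_flux")
  expect_error(process_schedule(20, 70, 0.6), "T0")
  expect_error(process_schedule(70, 20, -0.6), "cooling_rate")
})

test_that("trajectory CSV export preserves the sampled state", {
  traj <- ref_batch()
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), nrow(traj$data))
  expect_equal(df$S, traj$data$S, tolerance = 1e-6)
  expect_equal(df$alpha_39, traj$alpha[, 40], tolerance = 1e-6)
})
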