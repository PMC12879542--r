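test_that("geometric grid satisfies the ratio-factor law and diameter mapping", {
  g <- build_grid(1e-6, 1000e-6, 40)
  expect_equal(g$V0, 5.23599e-19, tolerance = 1e-5)
  expect_equal(g$q, 0.7665988, tolerance = 1e-6)
  ratios <- g$Vi[-1] / g$Vi[-g$n_bins]
  expect_equal(ratios, rep(2^g$q, g$n_bins - 1), tolerance = 1e-12)
  expect_equal(g$di, (6 * g$Vi / pi)^(1 / 3))
  expect_true(all(diff(g$di) > 0))
  expect_equal(g$di[1], 1e-6)
  expect_equal(g$di[g$n_bins], 1000e-6)
})

test_that("an integer ratio factor of 3 doubles consecutive diameters", {
  g <- build_grid(1e-6, 16e-6, 5)  # spans 2^4 in diameter
  expect_equal(g$q, 3)
  expect_equal(g$di[-1] / g$di[-5], rep(2, 4), tolerance = 1e-12)
})

test_that("grid construction rejects invalid bounds", {
  expect_error(build_grid(0, 1e-3, 10))
  expect_error(build_grid(1e-3, 1e-6, 10))
  expect_error(build_grid(1e-6, 1e-3, 1))
})

test_that("crystal population bookkeeping keeps alpha, N and f consistent", {
  g <- build_grid(1e-6, 1000e-6, 40)
  a <- numeric(40); a[c(5, 12, 30)] <- c(1e-4, 3e-4, 6e-4)
  pop <- crystal_population(a, g)
  expect_equal(pop$Ni * g$Vi, pop$alpha_i)
  expect_equal(sum(pop$fi), 1)
  expect_equal(pop$alpha_total, 1e-3)
  expect_error(crystal_population(-a, g))
  empty <- crystal_population(numeric(40), g)
  expect_equal(sum(empty$fi), 0)
})

test_that("volumetric growth rate is (pi/2) d^2 G and linear in G", {
  g <- build_grid(1e-6, 1000e-6, 40)
  expect_equal(volumetric_growth_rate(0, g), numeric(40))
  Gv <- volumetric_growth_rate(1e-8, g)
  expect_equal(Gv, pi / 2 * g$di^2 * 1e-8)
  expect_equal(volumetric_growth_rate(2e-8, g), 2 * Gv)
  # frozen spot value for a 100 um crystal
  g2 <- build_grid(100e-6, 200e-6, 2)
  expect_equal(volumetric_growth_rate(1e-8, g2)[1], 1.5708e-16,
               tolerance = 1e-4)
})

test_that("discrete growth term conserves particle number and matches brute-force re-summation", {
  g <- build_grid(1e-6, 1000e-6, 40)
  a <- numeric(40); a[c(8, 15, 16, 22)] <- c(2e-5, 5e-5, 1e-5, 3e-5)
  pop <- crystal_population(a, g)
  G <- 2e-8
  da <- growth_rates(pop, g, G)
  # independent bin-by-bin re-summation of the upwind transfer terms
  Ni <- pop$Ni
  Gv <- 3 * g$Vi / g$di * G
  oracle <- numeric(40)
  for (i in 1:40) {
    inflow <- if (i > 1) Gv[i - 1] * Ni[i - 1] / (g$Vi[i] - g$Vi[i - 1]) else 0
    outflow <- if (i < 40) Gv[i] * Ni[i] / (g$Vi[i + 1] - g$Vi[i]) else 0
    oracle[i] <- g$Vi[i] * (inflow - outflow)
  }
  expect_equal(da, oracle)
  # total number is conserved (telescoping sum, closed boundaries)
  expect_lt(abs(sum(da / g$Vi)) / sum(Ni), 1e-12)
  # total volume production equals the sum of per-bin deposition terms
  expect_equal(sum(da), sum(Gv[-40] * Ni[-40]), tolerance = 1e-12)
})

test_that("growth moves a monodisperse population up, not down", {
  g <- build_grid(1e-6, 1000e-6, 40)
  a <- numeric(40); a[10] <- 1e-4
  da <- growth_rates(crystal_population(a, g), g, 1e-8)
  expect_lt(da[10], 0)
  expect_gt(da[11], 0)
  expect_true(all(da[-c(10, 11)] == 0))
  # empty population: nothing happens
  expect_equal(growth_rates(crystal_population(numeric(40), g), g, 1e-8),
               numeric(40))
})

test_that("a loaded top bin triggers the truncation warning", {
  g <- build_grid(1e-6, 1000e-6, 40)
  a <- numeric(40); a[40] <- 1e-4; a[20] <- 1e-4
  expect_warning(growth_rates(crystal_population(a, g), g, 1e-8),
                 "truncation")
})

test_that("nucleation feeds only the smallest bin at rate V0 ndot0", {
  g <- build_grid(1e-6, 1000e-6, 40)
  expect_equal(nucleation_rates(0, g), numeric(40))
  da <- nucleation_rates(1.1e6, g)
  expect_equal(da[1], 5.76e-13, tolerance = 1e-3)
  expect_true(all(da[-1] == 0))
  # number source: da0/V0 returns the imposed nucleation rate
  expect_equal(da[1] / g$V0, 1.1e6)
})

test_that("Sauter mean diameter matches hand-computed cases and stays within occupied bins", {
  g2 <- build_grid(100e-6, 200e-6, 2)   # bins at exactly 100 and 200 um
  # monodisperse
  pop <- crystal_population(c(1e-4, 0), g2)
  expect_equal(sauter_mean_diameter(pop), 100e-6)
  # equal numbers at 100 and 200 um -> 180 um
  N <- 1e9
  pop <- crystal_population(N * g2$Vi, g2)
  expect_equal(sauter_mean_diameter(pop), 180e-6)
  # bounds for an arbitrary population
  g <- build_grid(1e-6, 1000e-6, 40)
  a <- numeric(40); a[5:20] <- stats::runif(16)
  d32 <- sauter_mean_diameter(crystal_population(a, g))
  expect_gt(d32, g$di[5]); expect_lt(d32, g$di[20])
  expect_error(sauter_mean_diameter(crystal_population(numeric(40), g)),
               "empty")
})

test_that("under constant growth the mean diameter advances at close to G on a fine grid", {
  # monodisperse seed grown one decade of size on an 80-bin grid; the
  # volume-weighted mean should advance at a rate near G (numerical
  # diffusion of the upwind scheme accounts for the tolerance)
  g <- build_grid(1e-6, 1000e-6, 80)
  a0 <- numeric(80)
  j <- which.min(abs(g$di - 10e-6))
  a0[j] <- 1e-5
  G <- 1e-8
  t_end <- (100e-6 - g$di[j]) / G
  rhs <- function(t, y, p)
    list(crystalpbe:::.growth_rates_raw(y, g, G))
  out <- deSolve::ode(a0, c(0, t_end), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-18)
  af <- pmax(out[2, -1], 0)
  d43 <- function(a) sum(a * g$di) / sum(a)     # volume-weighted mean
  advance <- d43(af) - d43(a0)
  expect_lt(abs(advance - G * t_end) / (G * t_end), 0.15)
  # particle number conserved through the integration
  expect_equal(sum(af / g$Vi), sum(a0 / g$Vi), tolerance = 1e-8)
})

test_that("population CSV round trip preserves the population", {
  g <- build_grid(1e-6, 1000e-6, 40)
  pop <- fixture_seeded_population(g, median_d = 80e-6, sdlog = 0.4,
                                   total_alpha = 2e-4)
  f <- tempfile(fileext = ".csv")
  write_population_csv(pop, f)
  pop2 <- read_population_csv(f)
  expect_equal(pop2$alpha_i, pop$alpha_i, tolerance = 1e-12)
  expect_equal(pop2$grid$Vi, pop$grid$Vi, tolerance = 1e-12)
})
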