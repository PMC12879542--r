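#' Synthetic growth-rate dataset
#'
#' Draws relative supersaturations log-uniformly on \code{sigma_range} and
#' generates growth rates from the power law \eqn{G = k_G \sigma^g}
#' perturbed by multiplicative lognormal noise
#' (\eqn{G \times e^{\epsilon}}, \eqn{\epsilon \sim N(0, sd^2)}).
#' \code{noise_sd = 0} yields exact power-law data. The same seed always
#' produces the same dataset.
#'
#' @param seed integer RNG seed.
#' @param n number of records.
#' @param kG,g generating power-law parameters.
#' @param sigma_range range of relative supersaturation (both ends > 0).
#' @param noise_sd standard deviation of the log-scale noise.
#' @return A data.frame with columns \code{sigma}, \code{G} (class
#'   \code{growth_dataset}).
#' @export
fixture_growth_dataset <- function(seed, n = 50, kG = 2.80e-7, g = 1.43,
                                   sigma_range = c(0.05, 1),
                                   noise_sd = 0.1) {
  stopifnot(n >= 1, all(sigma_range > 0), noise_sd >= 0)
  set.seed(seed)
  sigma <- exp(stats::runif(n, log(sigma_range[1]), log(sigma_range[2])))
  G <- kG * sigma^g
  if (noise_sd > 0) G <- G * exp(stats::rnorm(n, 0, noise_sd))
  structure(data.frame(sigma = sigma, G = G),
            class = c("growth_dataset", "data.frame"))
}

#' Deterministic seeded crystal population (lognormal in diameter)
#'
#' Places a lognormal volume distribution on the grid: the crystal volume
#' fraction in each bin is the lognormal volume-density mass between the
#' bin's geometric edges, scaled to \code{total_alpha}.
#'
#' @param grid a \code{\link{build_grid}} result.
#' @param median_d median diameter of the volume distribution (m).
#' @param sdlog lognormal log-scale standard deviation.
#' @param total_alpha total crystal volume fraction of the seeds.
#' @param rho_s crystal density (kg/m^3).
#' @return A \code{\link{crystal_population}}.
#' @export
fixture_seeded_population <- function(grid, median_d = 50e-6, sdlog = 0.3,
                                      total_alpha = 1e-4, rho_s = 1540) {
  stopifnot(inherits(grid, "volume_grid"), median_d > 0, sdlog > 0,
            total_alpha > 0)
  d <- grid$di
  n <- grid$n_bins
  r <- d[2] / d[1]
  edges <- c(d[1] / sqrt(r), sqrt(d[-n] * d[-1]), d[n] * sqrt(r))
  cdf <- stats::plnorm(edges, meanlog = log(median_d), sdlog = sdlog)
  w <- diff(cdf)
  if (sum(w) <= 0) stop("seed distribution has no mass on the grid")
  crystal_population(total_alpha * w / sum(w), grid, rho_s = rho_s)
}

#' Equilibrium-case run configuration
#'
#' A configuration whose initial concentration equals the solubility at
#' the initial temperature: with no cooling the state is an exact fixed
#' point of the simulator.
#'
#' @param T0 initial (and saturation) temperature, degC.
#' @param solub a \code{\link{solubility_model}}.
#' @return A \code{\link{run_config}} list.
#' @export
fixture_equilibrium_case <- function(T0 = 45, solub = solubility_model()) {
  run_config(list(
    schedule = list(T0 = T0, T_final = T0 - 1e-9, cooling_rate = 1e-12),
    solver = list(t_end = 3600),
    basis = list(C0 = solubility(T0, solub))))
}

#' Generate a fixture from a declarative spec
#'
#' Writes one of the synthetic fixtures to \code{dir}:
#' \code{growth_dataset} (CSV \code{sigma,G_m_per_s}),
#' \code{seeded_population} (population CSV), or
#' \code{equilibrium_case} (YAML run configuration). Identical specs
#' (including seed) produce byte-identical files.
#'
#' @param spec list with \code{seed}, \code{kind} (one of
#'   \code{"growth_dataset"}, \code{"seeded_population"},
#'   \code{"equilibrium_case"}) and kind-specific \code{parameters}.
#' @param dir output directory.
#' @return Invisibly, the path of the file written.
#' @export
make_fixture <- function(spec, dir = ".") {
  stopifnot(is.list(spec), !is.null(spec$kind))
  kind <- match.arg(spec$kind, c("growth_dataset", "seeded_population",
                                 "equilibrium_case"))
  p <- spec$parameters
  if (is.null(p)) p <- list()
  path <- switch(kind,
    growth_dataset = {
      if (is.null(spec$seed)) stop("growth_dataset fixture needs a seed")
      ds <- do.call(fixture_growth_dataset, c(list(seed = spec$seed), p))
      f <- file.path(dir, sprintf("growth_dataset_seed%d.csv", spec$seed))
      write_growth_dataset(ds, f)
      f
    },
    seeded_population = {
      grid_p <- p$grid
      if (is.null(grid_p)) grid_p <- list(d_min = 1e-6, d_max = 1000e-6,
                                          n_bins = 40)
      grid <- build_grid(grid_p$d_min, grid_p$d_max, grid_p$n_bins)
      p$grid <- NULL
      pop <- do.call(fixture_seeded_population, c(list(grid = grid), p))
      f <- file.path(dir, "seeded_population.csv")
      write_population_csv(pop, f)
      f
    },
    equilibrium_case = {
      cfg <- do.call(fixture_equilibrium_case, p)
      f <- file.path(dir, "equilibrium_case.yaml")
      write_run_config(cfg, f)
      f
    })
  invisible(path)
}

#' Read/write growth-rate datasets as CSV
#'
#' Two-column CSV with header \code{sigma,G_m_per_s}.
#'
#' @param data a data.frame with columns \code{sigma}, \code{G}.
#' @param path file path.
#' @export
write_growth_dataset <- function(data, path) {
  df <- data.frame(sigma = data$sigma, G_m_per_s = data$G)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_dataset
#' @export
read_growth_dataset <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("sigma", "G_m_per_s") %in% names(df)))
    stop("growth dataset CSV must have columns 'sigma,G_m_per_s'")
  structure(data.frame(sigma = df$sigma, G = df$G_m_per_s),
            class = c("growth_dataset", "data.frame"))
}
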