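#' Geometric crystal-volume grid for the discrete method
#'
#' Builds the ratio-factor grid of the method of classes: bin volumes obey
#' \deqn{V_{i+1}/V_i = 2^q}
#' with \eqn{V_0 = (\pi/6) d_{min}^3} and \eqn{q} chosen so that the last
#' bin volume equals \eqn{(\pi/6) d_{max}^3}. Bin diameters are
#' volume-equivalent sphere diameters \eqn{d_i = (6 V_i/\pi)^{1/3}}.
#' The ratio factor is real-valued; an integer \code{q} (the coarsest
#' classical choice) is a special case.
#'
#' @param d_min,d_max smallest and largest bin diameter (m).
#' @param n_bins number of size classes, \code{>= 2}.
#' @return An object of class \code{volume_grid}: list with \code{V0},
#'   \code{q}, \code{n_bins}, \code{Vi} (m^3), \code{di} (m).
#' @examples
#' g <- build_grid(1e-6, 1000e-6, 40)
#' g$q  # about 0.7666
#' @export
build_grid <- function(d_min, d_max, n_bins) {
  if (!(is.numeric(d_min) && is.numeric(d_max) && d_min > 0 &&
        d_max > d_min))
    stop("require 0 < d_min < d_max")
  if (!(n_bins >= 2))
    stop("n_bins must be >= 2")
  n_bins <- as.integer(n_bins)
  V0 <- pi / 6 * d_min^3
  Vmax <- pi / 6 * d_max^3
  q <- log2(Vmax / V0) / (n_bins - 1)
  Vi <- V0 * 2^(q * (seq_len(n_bins) - 1))
  structure(
    list(V0 = V0, q = q, n_bins = n_bins, Vi = Vi,
         di = (6 * Vi / pi)^(1 / 3)),
    class = "volume_grid")
}

#' Crystal population on a volume grid
#'
#' Holds the per-bin crystal volume fractions \eqn{\alpha_i} (crystal volume
#' per unit slurry volume). Number densities \eqn{N_i = \alpha_i/V_i} and
#' volume-normalised fractions \eqn{f_i = \alpha_i/\alpha} with
#' \eqn{\alpha = \sum_i \alpha_i} are derived on access.
#'
#' @param alpha_i numeric vector of per-bin volume fractions (length
#'   \code{grid$n_bins}, all \code{>= 0}).
#' @param grid a \code{\link{build_grid}} result.
#' @param rho_s crystal density (kg/m^3); defaults to 1540, a literature
#'   value for the alpha polymorph of L-glutamic acid.
#' @return An object of class \code{crystal_population} with fields
#'   \code{alpha_i}, \code{Ni}, \code{fi}, \code{alpha_total}, \code{rho_s}
#'   and the grid.
#' @export
crystal_population <- function(alpha_i, grid, rho_s = 1540) {
  stopifnot(inherits(grid, "volume_grid"),
            length(alpha_i) == grid$n_bins,
            all(alpha_i >= 0), rho_s > 0)
  total <- sum(alpha_i)
  structure(
    list(alpha_i = alpha_i,
         Ni = alpha_i / grid$Vi,
         fi = if (total > 0) alpha_i / total else rep(0, grid$n_bins),
         alpha_total = total,
         rho_s = rho_s,
         grid = grid),
    class = "crystal_population")
}

#' Volume-based growth rate per bin
#'
#' Converts the linear growth rate \code{G} (rate of change of the
#' volume-equivalent diameter, m/s) into the volumetric growth rate of each
#' bin, \eqn{G_{v,i} = 3 V_i G / d_i = (\pi/2) d_i^2 G} (m^3/s), i.e.
#' \eqn{dV/dt} of a sphere whose diameter grows at rate \code{G}.
#'
#' @param G linear growth rate (m/s), \code{>= 0}.
#' @param grid a \code{\link{build_grid}} result.
#' @return Numeric vector of per-bin volumetric growth rates (m^3/s).
#' @export
volumetric_growth_rate <- function(G, grid) {
  stopifnot(inherits(grid, "volume_grid"), G >= 0)
  3 * grid$Vi / grid$di * G
}

#' Discrete growth term of the population balance
#'
#' Upwind, growth-only transfer between adjacent size classes:
#' \deqn{d\alpha_i/dt = V_i\left[\frac{G_{v,i-1} N_{i-1}}{V_i - V_{i-1}}
#'   - \frac{G_{v,i} N_i}{V_{i+1} - V_i}\right]}
#' with no inflow for the smallest bin and no outflow for the largest
#' (closed top boundary — the scheme conserves total particle number
#' exactly; growth only redistributes number while producing crystal
#' volume). A warning is emitted when more than 1\% of the crystal volume
#' sits in the top bin, signalling truncation of the size domain.
#'
#' @param pop a \code{\link{crystal_population}}.
#' @param grid a \code{\link{build_grid}} result.
#' @param G linear growth rate (m/s), \code{>= 0}.
#' @param warn_truncation emit the top-bin warning (default TRUE; the batch
#'   integrator disables it per-call and audits instead).
#' @return Numeric vector \eqn{d\alpha_i/dt} (1/s).
#' @export
growth_rates <- function(pop, grid = pop$grid, G, warn_truncation = TRUE) {
  stopifnot(inherits(pop, "crystal_population"), G >= 0)
  da <- .growth_rates_raw(pop$alpha_i, grid, G)
  if (warn_truncation && pop$alpha_total > 0 &&
      pop$alpha_i[grid$n_bins] > 0.01 * pop$alpha_total)
    warning("top size bin holds > 1% of crystal volume: grid truncation risk")
  da
}

# bare-vector kernel shared with the ODE right-hand sides
.growth_rates_raw <- function(alpha_i, grid, G) {
  n <- grid$n_bins
  Ni <- pmax(alpha_i, 0) / grid$Vi
  Gv <- 3 * grid$Vi / grid$di * G
  flux <- Gv * Ni / (c(grid$Vi[-1], NA) - grid$Vi)  # flux out of bin i
  flux[n] <- 0                                      # closed top boundary
  grid$Vi * (c(0, flux[-n]) - flux)
}

#' Nucleation source term of the population balance
#'
#' New crystals are born into the smallest size class at volume \eqn{V_0}:
#' \eqn{d\alpha_0/dt = V_0 \dot n_0}; all other bins receive nothing.
#'
#' @param ndot0 nucleation rate (#/m^3 s), \code{>= 0}.
#' @param grid a \code{\link{build_grid}} result.
#' @return Numeric vector \eqn{d\alpha_i/dt} (1/s), non-zero only in bin 1.
#' @export
nucleation_rates <- function(ndot0, grid) {
  stopifnot(inherits(grid, "volume_grid"), ndot0 >= 0)
  da <- numeric(grid$n_bins)
  da[1] <- grid$V0 * ndot0
  da
}

#' Sauter mean diameter of a population
#'
#' \eqn{d_{32} = \sum_i N_i d_i^3 / \sum_i N_i d_i^2}, the
#' surface-area-weighted mean crystal size.
#'
#' @param pop a \code{\link{crystal_population}} with positive total volume.
#' @param grid a \code{\link{build_grid}} result.
#' @return Sauter mean diameter (m).
#' @export
sauter_mean_diameter <- function(pop, grid = pop$grid) {
  stopifnot(inherits(pop, "crystal_population"))
  if (pop$alpha_total <= 0)
    stop("Sauter mean diameter undefined for an empty population")
  sum(pop$Ni * grid$di^3) / sum(pop$Ni * grid$di^2)
}

#' Write / read a crystal population as CSV
#'
#' Serialises per-bin diameters, volumes, volume fractions and number
#' densities with columns \code{bin_index,d_m,V_m3,alpha_i,N_i}.
#'
#' @param pop a \code{\link{crystal_population}}.
#' @param path file path.
#' @export
write_population_csv <- function(pop, path) {
  g <- pop$grid
  utils::write.csv(
    data.frame(bin_index = seq_len(g$n_bins) - 1L, d_m = g$di, V_m3 = g$Vi,
               alpha_i = pop$alpha_i, N_i = pop$Ni),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @param grid the grid to attach; if NULL it is rebuilt from the stored
#'   diameters' extremes and bin count.
#' @param rho_s crystal density (kg/m^3).
#' @export
read_population_csv <- function(path, grid = NULL, rho_s = 1540) {
  df <- utils::read.csv(path)
  if (is.null(grid))
    grid <- build_grid(df$d_m[1], df$d_m[nrow(df)], nrow(df))
  crystal_population(df$alpha_i, grid, rho_s = rho_s)
}
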