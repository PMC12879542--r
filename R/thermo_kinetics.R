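#' Quadratic solubility model for alpha-LGA in water
#'
#' Constructs the equilibrium solubility polynomial
#' \deqn{C^*(T') = a_0 - a_1 T' + a_2 T'^2}
#' where \eqn{C^*} is the saturation mole fraction of solute
#' (mol LGA / mol solution) and \eqn{T'} is the temperature transformed
#' according to \code{temp_convention}: the input temperature in degrees
#' Celsius is used as printed (\code{"celsius_as_printed"}) or shifted to
#' absolute kelvin (\code{"absolute_kelvin"}, the default).
#'
#' With the default alpha-LGA coefficients, only the kelvin convention gives
#' a solubility curve that increases with temperature over the operating
#' range 10--80 degC, which is the physically correct behaviour for
#' L-glutamic acid; the Celsius reading is retained for literal reproduction
#' of the printed polynomial.
#'
#' @param a0,a1,a2 polynomial coefficients (mole-fraction units; note the
#'   minus sign on \code{a1} in the formula above).
#' @param temp_convention \code{"absolute_kelvin"} or
#'   \code{"celsius_as_printed"}.
#' @param validity_window numeric length-2, temperature window in degC over
#'   which evaluations are considered trustworthy. Evaluations outside it
#'   warn; a non-positive solubility anywhere is an error.
#' @return An object of class \code{solubility_model}.
#' @examples
#' sol <- solubility_model()
#' solubility(20, sol)  # saturation mole fraction at 20 degC
#' @export
solubility_model <- function(a0 = 0.08131, a1 = 0.000595783, a2 = 1.10258e-6,
                             temp_convention = c("absolute_kelvin",
                                                 "celsius_as_printed"),
                             validity_window = c(10, 80)) {
  temp_convention <- match.arg(temp_convention)
  stopifnot(is.numeric(a0), is.numeric(a1), is.numeric(a2),
            length(validity_window) == 2L,
            validity_window[1] < validity_window[2])
  structure(
    list(a0 = a0, a1 = a1, a2 = a2,
         temp_convention = temp_convention,
         validity_window = as.numeric(validity_window)),
    class = "solubility_model")
}

# temperature in degC -> polynomial argument per the model's convention
.temp_transform <- function(T_celsius, model) {
  if (model$temp_convention == "absolute_kelvin") T_celsius + 273.15
  else T_celsius
}

#' Equilibrium saturation mole fraction at a temperature
#'
#' Evaluates the solubility polynomial at temperature \code{T} (degC).
#' Temperatures outside the model's validity window produce a warning;
#' a non-positive solubility is an error because the supersaturation ratio
#' \eqn{S = C/C^*} would be undefined.
#'
#' @param T temperature in degrees Celsius (vectorised).
#' @param model a \code{\link{solubility_model}}.
#' @return Saturation mole fraction(s), same length as \code{T}.
#' @export
solubility <- function(T, model = solubility_model()) {
  stopifnot(inherits(model, "solubility_model"), is.numeric(T))
  vw <- model$validity_window
  if (any(T < vw[1] | T > vw[2])) {
    warning(sprintf(
      "temperature(s) outside solubility validity window [%g, %g] degC",
      vw[1], vw[2]))
  }
  Tp <- .temp_transform(T, model)
  cstar <- model$a0 - model$a1 * Tp + model$a2 * Tp^2
  if (any(cstar <= 0)) {
    bad <- T[cstar <= 0][1]
    stop(sprintf("solubility is non-positive at T = %g degC", bad))
  }
  cstar
}

#' Supersaturation state of a solution
#'
#' Computes the supersaturation ratio \eqn{S = C/C^*(T)} and the relative
#' supersaturation \eqn{\sigma = S - 1}, the driving force of the nucleation
#' and growth power laws. \eqn{\sigma < 0} denotes an undersaturated
#' solution.
#'
#' @param C solute mole fraction (mol LGA / mol solution), \code{C >= 0}.
#' @param T temperature in degC.
#' @param model a \code{\link{solubility_model}}.
#' @return A list with components \code{C}, \code{T}, \code{Cstar},
#'   \code{S}, \code{sigma} (class \code{supersaturation_state}).
#' @export
supersaturation <- function(C, T, model = solubility_model()) {
  stopifnot(is.numeric(C), all(C >= 0))
  cstar <- solubility(T, model)
  S <- C / cstar
  structure(list(C = C, T = T, Cstar = cstar, S = S, sigma = S - 1),
            class = "supersaturation_state")
}

#' Power-law nucleation and growth kinetic parameters
#'
#' Bundles the rate constants and exponents of the primary nucleation rate
#' \eqn{\dot n_0 = k_N \sigma^n} (#/m^3 s) and the linear growth rate
#' \eqn{G = k_G \sigma^g} (m/s), with a free-text provenance label.
#'
#' Two published parameter sets for alpha-LGA are provided as presets:
#' \code{kinetics_tai_shei()} (6 L vessel, 600 rpm; the default simulation
#' kinetics) and \code{kinetics_penchev()} (20 L vessel, 100 rpm; growth
#' only, nucleation parameters shared with the former).
#'
#' @param kN nucleation rate constant (#/m^3 s), \code{>= 0}.
#' @param n nucleation exponent, \code{> 0}.
#' @param kG growth rate constant (m/s), \code{>= 0}.
#' @param g growth exponent, \code{> 0}.
#' @param source provenance label.
#' @return An object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(kN, n, kG, g, source = "user") {
  stopifnot(is.numeric(kN), kN >= 0, is.numeric(kG), kG >= 0,
            is.numeric(n), n > 0, is.numeric(g), g > 0)
  structure(list(kN = kN, n = n, kG = kG, g = g, source = source),
            class = "kinetic_params")
}

#' @rdname kinetic_params
#' @export
kinetics_tai_shei <- function() {
  kinetic_params(kN = 4.02e6, n = 1.87, kG = 9.76e-8, g = 2.34,
                 source = "Tai-Shei (6 L, 600 rpm)")
}

#' @rdname kinetic_params
#' @export
kinetics_penchev <- function() {
  kinetic_params(kN = 4.02e6, n = 1.87, kG = 2.80e-7, g = 1.43,
                 source = "Penchev growth (20 L, 100 rpm)")
}

#' Primary nucleation rate
#'
#' \eqn{\dot n_0 = k_N \sigma^n} for \eqn{\sigma > 0}; exactly zero for
#' \eqn{\sigma \le 0} (no nucleation without a driving force).
#'
#' @param sigma relative supersaturation (vectorised).
#' @param params a \code{\link{kinetic_params}}.
#' @return Nucleation rate(s) in #/m^3 s.
#' @export
nucleation_rate <- function(sigma, params) {
  stopifnot(inherits(params, "kinetic_params"))
  ifelse(sigma > 0, params$kN * sigma^params$n, 0)
}

#' Linear crystal growth rate
#'
#' \eqn{G = k_G \sigma^g} for \eqn{\sigma > 0}; exactly zero for
#' \eqn{\sigma \le 0} (dissolution is not modelled). \code{G} is the rate
#' of change of the volume-equivalent crystal diameter.
#'
#' @param sigma relative supersaturation (vectorised).
#' @param params a \code{\link{kinetic_params}}.
#' @return Growth rate(s) in m/s.
#' @export
growth_rate_linear <- function(sigma, params) {
  stopifnot(inherits(params, "kinetic_params"))
  ifelse(sigma > 0, params$kG * sigma^params$g, 0)
}

#' Fit a growth power law to (sigma, G) data
#'
#' Ordinary least squares of \eqn{\log G} on \eqn{\log \sigma}:
#' \eqn{k_G = \exp(\mathrm{intercept})}, \eqn{g = \mathrm{slope}}. Standard
#' errors are the OLS ones; the standard error of \eqn{k_G} is obtained by
#' the delta method, \eqn{\mathrm{se}(k_G) = k_G\,\mathrm{se(intercept)}}.
#'
#' @param data a data.frame with columns \code{sigma} and \code{G} (both
#'   strictly positive), or a \code{growth_dataset} from
#'   \code{\link{read_growth_dataset}}.
#' @return A list with \code{kG}, \code{g}, \code{se_kG}, \code{se_g},
#'   \code{fit} (the underlying \code{lm}).
#' @export
fit_growth_power_law <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("sigma", "G") %in% names(data)))
    stop("growth dataset must have columns 'sigma' and 'G'")
  if (nrow(data) < 3L)
    stop("at least 3 (sigma, G) records are required for the fit")
  if (any(data$sigma <= 0) || any(data$G <= 0))
    stop("log-log fit requires strictly positive sigma and G")
  fit <- stats::lm(log(G) ~ log(sigma), data = data)
  cf <- stats::coef(summary(fit))
  kG <- exp(cf[1, 1])
  list(kG = kG, g = cf[2, 1],
       se_kG = kG * cf[1, 2], se_g = cf[2, 2],
       fit = fit)
}

#' Saturation temperature for a given solute mole fraction
#'
#' Inverts the solubility polynomial: solves
#' \eqn{a_2 T'^2 - a_1 T' + (a_0 - C) = 0} and returns the root lying in the
#' model's validity window, converted back to degC. Errors if no real root
#' falls inside the window (e.g. \code{C} above the maximum solubility).
#'
#' @param C solute mole fraction.
#' @param model a \code{\link{solubility_model}}.
#' @return Saturation temperature in degC.
#' @export
saturation_temperature <- function(C, model = solubility_model()) {
  stopifnot(inherits(model, "solubility_model"), is.numeric(C),
            length(C) == 1L)
  disc <- model$a1^2 - 4 * model$a2 * (model$a0 - C)
  if (disc < 0)
    stop(sprintf("no real saturation temperature for C = %g", C))
  roots <- (model$a1 + c(-1, 1) * sqrt(disc)) / (2 * model$a2)
  vw <- .temp_transform(model$validity_window, model)
  inside <- roots >= vw[1] & roots <= vw[2]
  if (!any(inside))
    stop(sprintf("no saturation temperature in the validity window for C = %g",
                 C))
  Tp <- roots[inside][1]
  if (model$temp_convention == "absolute_kelvin") Tp - 273.15 else Tp
}
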