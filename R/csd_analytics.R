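#' Volume-based crystal size distribution
#'
#' Expresses a population as volume percent per size bin,
#' \eqn{100 f_i = 100 \alpha_i/\alpha}, against the bin diameters in
#' micrometres — the form in which final CSDs are usually reported and
#' measured (e.g. by ultrasonic attenuation spectrometry).
#'
#' @param pop a \code{\link{crystal_population}} with positive total
#'   crystal volume.
#' @param grid a \code{\link{build_grid}} result.
#' @return An object of class \code{volume_csd}: data.frame with columns
#'   \code{d_um} and \code{volume_percent} (summing to 100).
#' @export
volume_percent_csd <- function(pop, grid = pop$grid) {
  stopifnot(inherits(pop, "crystal_population"))
  if (pop$alpha_total <= 0)
    stop("CSD undefined for an empty population")
  structure(
    data.frame(d_um = grid$di * 1e6, volume_percent = 100 * pop$fi),
    class = c("volume_csd", "data.frame"))
}

#' Mode of a volume-based CSD
#'
#' Peak-bin diameter refined by log-parabolic interpolation: a parabola in
#' \eqn{\log d} is fitted through the peak bin and its two neighbours and
#' its vertex returned. A peak at either end of the grid is returned as
#' the bin diameter itself.
#'
#' @param csd a \code{\link{volume_percent_csd}} result.
#' @return Mode diameter in micrometres.
#' @export
csd_mode <- function(csd) {
  stopifnot(inherits(csd, "volume_csd"))
  v <- csd$volume_percent
  i <- which.max(v)
  n <- length(v)
  if (i == 1 || i == n) return(csd$d_um[i])
  x <- log(csd$d_um[(i - 1):(i + 1)])
  y <- v[(i - 1):(i + 1)]
  denom <- (y[1] - 2 * y[2] + y[3])
  if (denom >= 0) return(csd$d_um[i])  # not locally concave
  # vertex of the parabola through three (nearly) equispaced log-d points
  dx <- 0.5 * (x[3] - x[1])
  shift <- 0.5 * (y[1] - y[3]) / denom
  exp(x[2] + shift * dx)
}

#' Volume-weighted percentiles of a CSD
#'
#' d10, d50 and d90 by linear interpolation of the cumulative volume curve
#' in log-diameter, with cumulative values assigned to geometric bin
#' edges (consistent with the geometric grid).
#'
#' @param csd a \code{\link{volume_percent_csd}} result.
#' @param probs cumulative volume levels in percent.
#' @return Named numeric vector of diameters (micrometres).
#' @export
csd_percentiles <- function(csd, probs = c(10, 50, 90)) {
  stopifnot(inherits(csd, "volume_csd"))
  d <- csd$d_um
  v <- csd$volume_percent
  n <- length(d)
  r <- if (n > 1) d[2] / d[1] else 2
  # geometric bin edges bracketing each bin centre
  edges <- c(d[1] / sqrt(r), sqrt(d[-n] * d[-1]), d[n] * sqrt(r))
  cum <- c(0, cumsum(v))
  out <- vapply(probs, function(p) {
    j <- which(cum >= p)[1]
    if (j == 1) return(edges[1])
    frac <- (p - cum[j - 1]) / (cum[j] - cum[j - 1])
    exp(log(edges[j - 1]) + frac * (log(edges[j]) - log(edges[j - 1])))
  }, numeric(1))
  names(out) <- paste0("d", probs)
  out
}

#' Span of a CSD
#'
#' \eqn{(d_{90} - d_{10})/d_{50}}, a standard dimensionless width measure.
#'
#' @param csd a \code{\link{volume_percent_csd}} result.
#' @return The span (dimensionless).
#' @export
csd_span <- function(csd) {
  p <- csd_percentiles(csd)
  (p[["d90"]] - p[["d10"]]) / p[["d50"]]
}

#' L1 distance between two CSDs on a shared grid
#'
#' Half the L1 distance between volume-percent vectors: 0 for identical
#' distributions, 100 for fully disjoint ones.
#'
#' @param a,b \code{\link{volume_percent_csd}} results on the same
#'   diameter grid.
#' @return Distance in percent (0--100).
#' @export
csd_distance <- function(a, b) {
  stopifnot(inherits(a, "volume_csd"), inherits(b, "volume_csd"))
  if (length(a$d_um) != length(b$d_um) ||
      max(abs(log(a$d_um / b$d_um))) > 1e-9)
    stop("CSDs must share the same diameter grid")
  0.5 * sum(abs(a$volume_percent - b$volume_percent))
}

#' Write a CSD as CSV
#'
#' Columns \code{d_um,volume_percent}.
#'
#' @param csd a \code{\link{volume_percent_csd}} result.
#' @param path file path.
#' @export
write_csd_csv <- function(csd, path) {
  utils::write.csv(as.data.frame(csd)[, c("d_um", "volume_percent")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
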