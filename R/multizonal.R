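#' Compartment network of well-mixed zones
#'
#' Describes a reduced-order crystallizer as interconnected well-mixed
#' zones that exchange solution and crystals. \code{exchange_flows[z, z2]}
#' is the volumetric flow from zone z to zone z2 (m^3/s). Constant zone
#' volumes require flow balance: for every zone, total outflow equals
#' total inflow. Heat removal is split between zones by
#' \code{heat_weights} (non-negative, summing to 1); weights proportional
#' to zone volume reproduce a uniform temperature.
#'
#' @param zone_volumes numeric vector of zone volumes (m^3).
#' @param exchange_flows square matrix of inter-zone flows (m^3/s);
#'   off-diagonal entries \code{>= 0}, the diagonal is ignored.
#' @param heat_weights per-zone share of the total heat removal; defaults
#'   to volume-proportional (uniform temperature).
#' @return An object of class \code{zone_network}.
#' @export
zone_network <- function(zone_volumes, exchange_flows = NULL,
                         heat_weights = NULL) {
  nz <- length(zone_volumes)
  stopifnot(nz >= 1, all(zone_volumes > 0))
  if (is.null(exchange_flows)) exchange_flows <- matrix(0, nz, nz)
  exchange_flows <- as.matrix(exchange_flows)
  stopifnot(nrow(exchange_flows) == nz, ncol(exchange_flows) == nz)
  diag(exchange_flows) <- 0
  if (is.null(heat_weights)) heat_weights <- zone_volumes / sum(zone_volumes)
  stopifnot(length(heat_weights) == nz)
  structure(
    list(n_zones = nz, zone_volumes = as.numeric(zone_volumes),
         exchange_flows = exchange_flows,
         heat_weights = as.numeric(heat_weights)),
    class = "zone_network")
}

#' Validate a zone network
#'
#' Checks the constant-volume flow balance (per-zone inflow equals
#' outflow), non-negative off-diagonal flows, and heat weights that are
#' non-negative and sum to 1.
#'
#' @param net a \code{\link{zone_network}}.
#' @param tol relative tolerance for the flow balance.
#' @return A list with \code{ok} (logical) and \code{problems}
#'   (character vector naming offending zones/fields, empty when valid).
#' @export
validate_network <- function(net, tol = 1e-9) {
  stopifnot(inherits(net, "zone_network"))
  problems <- character(0)
  Q <- net$exchange_flows
  if (any(Q < 0))
    problems <- c(problems, "negative exchange flow(s)")
  out_f <- rowSums(Q)
  in_f <- colSums(Q)
  scale <- max(Q, 1e-300)
  bad <- which(abs(out_f - in_f) > tol * max(scale, out_f, in_f))
  if (length(bad))
    problems <- c(problems, sprintf(
      "flow imbalance in zone(s) %s (outflow != inflow)",
      paste(bad, collapse = ", ")))
  w <- net$heat_weights
  if (any(w < 0))
    problems <- c(problems, "negative heat weight(s)")
  if (abs(sum(w) - 1) > 1e-9)
    problems <- c(problems, sprintf("heat weights sum to %g, not 1", sum(w)))
  list(ok = length(problems) == 0L, problems = problems)
}

#' Three-zone stirred-crystallizer template
#'
#' A small preset network — top (near the free surface), bulk, and wall
#' (cooled) zones — qualitatively mirroring the heterogeneity of a cooled
#' stirred vessel: the wall zone takes a disproportionate share of the
#' heat removal, so supersaturation and nucleation peak there.
#'
#' @param solution_volume total solution volume (m^3).
#' @param circulation_flow circulating volumetric flow (m^3/s).
#' @param wall_heat_fraction share of heat removal assigned to the wall
#'   zone; the remainder is split volume-proportionally between top and
#'   bulk.
#' @return A \code{\link{zone_network}} with zones (top, bulk, wall).
#' @export
three_zone_template <- function(solution_volume, circulation_flow,
                                wall_heat_fraction = 0.6) {
  V <- solution_volume * c(0.15, 0.65, 0.20)
  Q <- matrix(0, 3, 3)
  # ring circulation top -> bulk -> wall -> top
  Q[1, 2] <- Q[2, 3] <- Q[3, 1] <- circulation_flow
  rest <- 1 - wall_heat_fraction
  w <- c(rest * V[1] / (V[1] + V[2]), rest * V[2] / (V[1] + V[2]),
         wall_heat_fraction)
  zone_network(V, Q, w)
}

#' Simulate a multizonal batch cooling crystallization
#'
#' Each zone integrates its local population balance and solute balance
#' (as \code{\link{simulate_batch}}) plus convective exchange of solute
#' and of every crystal size class with its neighbours at the
#' donor-zone composition. The imposed global cooling duty is split
#' between zones by the network's heat weights; zone temperatures then
#' evolve by local cooling plus convective heat exchange.
#'
#' @param net a valid \code{\link{zone_network}} whose volumes sum to
#'   \code{basis$solution_volume} (relative tolerance 1e-6).
#' @param schedule,kinetics,grid,solub,basis,rho_s,control as in
#'   \code{\link{simulate_batch}}.
#' @param seed_populations optional list of per-zone
#'   \code{\link{crystal_population}} seeds (NULL entries = unseeded).
#' @return A list of class \code{zonal_trajectory}: \code{$zones} is a
#'   list of per-zone \code{batch_trajectory} objects, \code{$averaged}
#'   the volume-averaged \code{batch_trajectory}, \code{$network} the
#'   network.
#' @export
simulate_zonal <- function(net, schedule, kinetics, grid,
                           solub = solubility_model(),
                           basis = solution_basis(),
                           seed_populations = NULL, rho_s = 1540,
                           control = solver_control()) {
  stopifnot(inherits(net, "zone_network"))
  v <- validate_network(net)
  if (!v$ok)
    stop("invalid zone network: ", paste(v$problems, collapse = "; "))
  if (abs(sum(net$zone_volumes) - basis$solution_volume) >
        1e-6 * basis$solution_volume)
    stop("zone volumes must sum to the basis solution volume")
  .check_solubility_positive(solub, schedule)
  nz <- net$n_zones
  nb <- grid$n_bins
  seed <- matrix(0, nz, nb)
  if (!is.null(seed_populations)) {
    stopifnot(length(seed_populations) == nz)
    for (z in seq_len(nz))
      if (!is.null(seed_populations[[z]]))
        seed[z, ] <- seed_populations[[z]]$alpha_i
  }
  core <- list(n_zones = nz, V = net$zone_volumes,
               Q = net$exchange_flows, w = net$heat_weights)
  res <- .integrate_network(core, schedule, kinetics, grid, solub, basis,
                            rho_s, seed, control)
  out <- res$out
  times <- res$times
  Tmat <- if (res$uniform_T)
    matrix(schedule_temperature(schedule, times), length(times), nz)
  else out[, 1 + res$iT, drop = FALSE]
  zones <- vector("list", nz)
  nL_tot <- 0
  alpha_avg <- matrix(0, length(times), nb)
  for (z in seq_len(nz)) {
    nL <- out[, 1 + z]
    cols <- 1 + nz + ((z - 1) * nb + 1):(z * nb)
    alpha <- out[, cols, drop = FALSE]
    zones[[z]] <- .make_trajectory(times, Tmat[, z], nL, res$n_w_z[z],
                                   alpha, grid, schedule, kinetics, solub,
                                   basis, rho_s, control,
                                   label = sprintf("zone %d", z))
    nL_tot <- nL_tot + nL
    alpha_avg <- alpha_avg + alpha * net$zone_volumes[z]
  }
  alpha_avg <- alpha_avg / res$Vtot
  Tavg <- as.vector(Tmat %*% net$zone_volumes) / res$Vtot
  averaged <- .make_trajectory(times, Tavg, nL_tot, basis$n_water,
                               alpha_avg, grid, schedule, kinetics, solub,
                               basis, rho_s, control,
                               label = "volume-averaged")
  structure(list(zones = zones, averaged = averaged, network = net),
            class = "zonal_trajectory")
}
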