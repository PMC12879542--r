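# Shared reference objects and memoised reference simulations.
# The reference batch is the 43 g/kg-water unseeded run, cooled 70 -> 20 degC
# at 0.6 K/min on a 40-bin 1-1000 um geometric grid.

ref_grid <- function(n_bins = 40) build_grid(1e-6, 1000e-6, n_bins)

ref_schedule <- function() process_schedule(70, 20, 0.6)

.ref_cache <- new.env(parent = emptyenv())

# memoised reference simulations keyed by the varying arguments
ref_batch <- function(n_bins = 40, rtol = 1e-8, t_end = NULL,
                      kinetics = kinetics_tai_shei()) {
  key <- paste("batch", n_bins, rtol, format(t_end), kinetics$source,
               sep = "|")
  if (is.null(.ref_cache[[key]])) {
    .ref_cache[[key]] <- simulate_batch(
      ref_schedule(), kinetics, ref_grid(n_bins),
      control = solver_control(rtol = rtol, t_end = t_end))
  }
  .ref_cache[[key]]
}

# trapezoid rule, used as an independent quadrature oracle
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
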