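# Independent oracles. These deliberately avoid the package's closed-form
# code paths: travel times come from explicit time stepping through the rate
# field, coverage from a discrete-event sweep over an initiation grid, and
# interval counting from per-base expansion.

# Brute-force travel time: step a polymerase through (lengths_bp, rates)
# with a fixed time step; returns the time at which it passes x.
oracle_travel_time <- function(lengths_bp, rates_kb_min, x, dt = 0.01) {
  stopifnot(x <= sum(lengths_bp))
  bounds <- cumsum(lengths_bp)
  pos <- 0
  t <- 0
  repeat {
    if (pos >= x) return(t)
    seg <- which(pos < bounds)[1]
    pos <- pos + rates_kb_min[seg] * 1000 * dt
    t <- t + dt
  }
}

# Discrete-event coverage oracle: polymerases initiate on a regular grid of
# candidate times with weight I(t0) * dt; position x receives weight from
# every initiation whose transit puts it at x inside the labeling window.
# tau_fun maps bp -> min and is supplied by the caller (use the stepping
# oracle above for full independence).
oracle_expected_coverage <- function(rate_fun, tau, window, dt = 0.01,
                                     t_lo = NULL) {
  t_lo <- t_lo %||% (window[1] - max(tau) - 1)
  t0 <- seq(t_lo, window[2], by = dt)
  w <- rate_fun(t0) * dt
  vapply(tau, function(tx) {
    sum(w[t0 + tx >= window[1] & t0 + tx <= window[2]])
  }, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Step-function initiation rate for the oracle, mirroring init_profile's
# semantics but built directly from (times, rates).
oracle_rate_fun <- function(times, rates) {
  function(t) rates[findInterval(t, times) + 1]
}

# Per-base brute-force interval count: expands binned coverage to single
# bases (each base carries count / bin_width) and sums over the interval.
oracle_count_reads <- function(cov, chrom, interval) {
  cov <- cov[cov$chrom == chrom, , drop = FALSE]
  if (!nrow(cov)) return(0)
  total <- 0
  for (i in seq_len(nrow(cov))) {
    bases <- seq(cov$start[i], cov$end[i] - 1)
    inside <- bases >= interval[1] & bases < interval[2]
    total <- total + sum(inside) * cov$count[i] / (cov$end[i] - cov$start[i])
  }
  total
}
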