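# Shared fixtures: small kinetic/tether parameter sets and compact simulated
# experiments, all built in code at test time.

kin_slow <- function() kinetic_params(k0_off = 0.2, x_beta = 0.3)
kin_fast <- function() kinetic_params(k0_off = 1.26, x_beta = 0.3)

quick_config <- function(kin = kin_slow(), seed = 1, ...) {
  simulation_config(kin, seed = seed, ...)
}

# Noiseless, rupture-free tether pulling (hazard effectively off) for
# deterministic force-path checks.
noiseless_config <- function(seed = 1, ...) {
  simulation_config(kinetic_params(1e-12, 0.3), noise_sd = 0, lc_sd_frac = 0,
                    seed = seed, ...)
}

# Build a synthetic candidate event for a curve at a chosen index.
event_at <- function(curve, i) {
  fb <- curve$force - stats::median(curve$force[(length(curve$force) * 0.9):length(curve$force)])
  list(curve_id = curve$curve_id, rupture_force = fb[i], rupture_index = i,
       pulling_velocity = curve$pulling_velocity)
}

# Exhaustive optimal 1-D k-means by enumeration of contiguous partitions of
# the sorted data (the optimum of 1-D k-means is always contiguous).
brute_force_wss <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  wss_seg <- function(v) sum((v - mean(v))^2)
  if (k == 1L) return(wss_seg(xs))
  best <- Inf
  splits <- utils::combn(n - 1L, k - 1L)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0L, splits[, j], n)
    tot <- 0
    for (s in seq_len(k)) tot <- tot + wss_seg(xs[(cuts[s] + 1L):cuts[s + 1L]])
    if (tot < best) best <- tot
  }
  best
}
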