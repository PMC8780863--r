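# Trajectory cache shared across test files: the calibrated simulations are
# deterministic, so each condition is integrated once per test run.
.traj_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.traj_cache[[key]])) .traj_cache[[key]] <- force(expr)
  .traj_cache[[key]]
}

# standard post-transient discard used by the analysis defaults
std_discard <- function(half_period) max(96, 5 * 2 * half_period)

dd_traj <- function(dt = 0.01) {
  cached(paste0("dd", dt),
         simulate_clock(default_parameters(), ld_constant(0), 600, dt = dt))
}

ld_traj <- function(half_period, n_cycles = 20, dt = 0.01, intensity = 1) {
  key <- paste0("ld", half_period, "_", n_cycles, "_", dt, "_", intensity)
  cached(key, {
    T <- 2 * half_period
    simulate_clock(default_parameters(), symmetric_ld(half_period, intensity),
                   std_discard(half_period) + n_cycles * T, dt = dt)
  })
}

sinusoid_series <- function(period, duration, dt = 0.1, phase = 0,
                            noise_sd = 0, seed = NULL) {
  t <- seq(0, duration, by = dt)
  x <- sin(2 * pi * (t - phase) / period)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + rnorm(length(t), 0, noise_sd)
  }
  data.frame(time = t, value = x)
}
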