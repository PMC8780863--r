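# Seeded synthetic-data generators. Each generator restores the caller's
# RNG state, so fixtures are reproducible from the seed argument alone.

with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Synthetic FRQ densitometry
#'
#' Emulates blot densitometry: simulates the model under `protocol`, samples
#' the chosen component every `interval` hours over `duration` hours
#' (starting after `settle` hours), applies multiplicative log-normal noise
#' (blot intensities are positive and their errors scale with signal) and
#' rescales the series to a maximum of 1. With `noise_sd = 0` the samples
#' equal the trajectory values up to that normalization.
#'
#' @param protocol an `ld_protocol`.
#' @param params a `clock_parameters` object.
#' @param interval sampling interval (h); must be at least `dt`.
#' @param noise_sd SD of the log-normal noise on the log scale.
#' @param seed integer seed.
#' @param duration length of the sampled window (h).
#' @param settle simulated time discarded before the window starts (h).
#' @param component state variable to sample.
#' @param dt integration step (h).
#' @return A (`time`, `value`) data.frame; time 0 is the start of the
#'   sampled window.
#' @export
gen_densitometry <- function(protocol, params = default_parameters(),
                             interval = 3, noise_sd = 0.1, seed = 1,
                             duration = 48, settle = 0, component = "F",
                             dt = 0.01) {
  if (interval < dt) stop("interval must be >= the integration step dt",
                          call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  traj <- simulate_clock(params, protocol, settle + duration, dt = dt)
  t_samp <- seq(settle, settle + duration, by = interval)
  base <- stats::approx(traj$times, traj$states[, component],
                        xout = t_samp)$y
  noisy <- with_seed(seed, base * exp(rnorm(length(base), 0, noise_sd)))
  data.frame(time = t_samp - settle, value = noisy / max(noisy))
}

#' Synthetic race-tube record
#'
#' Growth-front marks every 24 h at `growth_speed` with small positional
#' jitter, and conidiation band centers at times `period, 2*period, ...`
#' mapped to positions through the (jittered) growth curve, again with
#' jitter. Band timing is driven directly by the forcing period — an
#' hourglass read-out, matching the observation that conidiation banding
#' under LD cycles does not require a functional core oscillator. If the
#' jitter disorders the bands, the bands are redrawn (up to 20 attempts)
#' with a warning.
#'
#' @param period banding period (h).
#' @param growth_speed linear growth speed (mm/h).
#' @param days number of 24 h growth days (>= 2).
#' @param jitter_sd positional jitter SD (mm) for marks and bands.
#' @param seed integer seed.
#' @param condition label stored on the record.
#' @return A `race_tube_record`.
#' @export
gen_race_tube <- function(period, growth_speed = 1.5, days = 7,
                          jitter_sd = 0.2, seed = 1, condition = "") {
  if (period <= 0 || growth_speed <= 0) stop("period and growth_speed must ",
                                             "be positive", call. = FALSE)
  if (days < 2) stop("need days >= 2", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  with_seed(seed, {
    t_marks <- 24 * (0:days)
    marks <- t_marks * growth_speed +
      c(0, rnorm(days, 0, jitter_sd)) # inoculation mark is exact
    if (is.unsorted(marks, strictly = TRUE))
      stop("mark jitter too large relative to daily growth", call. = FALSE)
    t_bands <- seq(period, days * 24, by = period)
    ideal <- stats::approx(t_marks, marks, xout = t_bands)$y
    for (try in 1:20) {
      bands <- ideal + rnorm(length(ideal), 0, jitter_sd)
      bands <- pmin(pmax(bands, marks[1]), marks[length(marks)])
      if (!is.unsorted(bands, strictly = TRUE)) break
      if (try == 20) {
        warning("band jitter disordered the bands; enforcing monotonicity ",
                "by sorting")
        bands <- sort(bands)
        bands <- bands + cumsum(c(0, diff(bands) == 0)) * 1e-6
      }
    }
    race_tube_record(marks, bands, condition = condition)
  })
}

#' Synthetic conidium morphometry
#'
#' Two-population aspect-ratio mixture: microconidia are nearly round
#' (length/width drawn uniformly in \[1.0, 1.4\]) and macroconidia elongated
#' (ratio log-uniform in \[2.0, 5.0\]); widths are log-normal around 2.5 um
#' (micro) and 5 um (macro). Each conidium is a microconidium with
#' probability `micro_fraction`, so the expected classified proportion
#' equals `micro_fraction`.
#'
#' @param n number of conidia (>= 1).
#' @param micro_fraction probability of the microconidium population.
#' @param seed integer seed.
#' @return A data.frame with columns `length_um`, `width_um`.
#' @export
gen_morphometry <- function(n, micro_fraction, seed = 1) {
  if (n < 1) stop("need n >= 1", call. = FALSE)
  if (micro_fraction < 0 || micro_fraction > 1)
    stop("micro_fraction must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    is_micro <- runif(n) < micro_fraction
    ratio <- ifelse(is_micro, runif(n, 1.0, 1.4),
                    exp(runif(n, log(2.0), log(5.0))))
    width <- ifelse(is_micro, rlnorm(n, log(2.5), 0.15),
                    rlnorm(n, log(5), 0.2))
    data.frame(length_um = ratio * width, width_um = width)
  })
}

#' Synthetic multi-condition phenotype panel
#'
#' Generates, per symmetric-LD condition, replicate race tubes (flat
#' growth-speed dependence on cycle length) and a conidium morphometry
#' sample with a configurable dependence of the microconidium fraction on
#' cycle length. The default `"peaked"` effect rises with half-period and is
#' maximal at 12 h, reflecting the reported maximum of microconidia
#' production under LD12:12; `"flat"` removes the dependence.
#'
#' @param half_periods symmetric half-periods (h), >= 3 conditions.
#' @param effect `"peaked"` or `"flat"` microconidia effect model.
#' @param n_conidia conidia measured per condition.
#' @param n_tubes replicate race tubes per condition.
#' @param growth_speed mean growth speed (mm/h), flat across conditions.
#' @param growth_cv coefficient of variation of per-tube growth speed.
#' @param seed integer seed.
#' @return List with `conditions` (data.frame: `half_period`,
#'   `cycle_length`, `micro_fraction_true`, `proportion`, `mean_growth`),
#'   `morphometry` (list of data.frames) and `tubes` (list of lists of
#'   `race_tube_record`s).
#' @export
gen_condition_panel <- function(half_periods = c(0.75, 1, 2, 3, 6, 12),
                                effect = c("peaked", "flat"),
                                n_conidia = 300, n_tubes = 3,
                                growth_speed = 1.5, growth_cv = 0.05,
                                seed = 1) {
  effect <- match.arg(effect)
  if (length(half_periods) < 3L) stop("need >= 3 conditions", call. = FALSE)
  micro_f <- if (effect == "peaked")
    0.08 + 0.24 * pmin(half_periods, 12) / 12 else rep(0.15,
                                                       length(half_periods))
  with_seed(seed, {
    sub_seeds <- sample.int(2^31 - 2, 2 * length(half_periods))
    morph <- vector("list", length(half_periods))
    tubes <- vector("list", length(half_periods))
    prop <- mean_growth <- numeric(length(half_periods))
    for (i in seq_along(half_periods)) {
      morph[[i]] <- gen_morphometry(n_conidia, micro_f[i],
                                    seed = sub_seeds[2 * i - 1])
      prop[i] <- microconidia_proportion(morph[[i]])
      speeds <- growth_speed * exp(rnorm(n_tubes, 0, growth_cv))
      tubes[[i]] <- lapply(seq_len(n_tubes), function(j)
        gen_race_tube(2 * half_periods[i], speeds[j], days = 6,
                      jitter_sd = 0.2,
                      seed = sub_seeds[2 * i] + j,
                      condition = sprintf("LD%g:%g", half_periods[i],
                                          half_periods[i])))
      mean_growth[i] <- mean(vapply(tubes[[i]], function(r)
        mean(daily_growth(r)), numeric(1)))
    }
    list(conditions = data.frame(half_period = half_periods,
                                 cycle_length = 2 * half_periods,
                                 micro_fraction_true = micro_f,
                                 proportion = prop,
                                 mean_growth = mean_growth),
         morphometry = morph, tubes = tubes)
  })
}
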