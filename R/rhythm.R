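#' Prominence-based peak detection
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence` times the series range. Prominence of a peak is its
#' height above the higher of the two valley floors separating it from the
#' nearest taller point on each side (or the series end). Plateau maxima are
#' reported at their first sample (ties broken toward earlier time);
#' endpoints are never peaks; a constant series yields no peaks. Peak times
#' are refined by a quadratic fit through the three samples around each
#' maximum, which recovers sub-sample peak positions on coarsely sampled
#' (e.g. 3-hourly densitometry) series.
#'
#' @param series a data.frame whose first two columns are time (h, strictly
#'   increasing) and value; at least 3 samples.
#' @param min_prominence required prominence as a fraction of
#'   `max(value) - min(value)`.
#' @param refine logical; quadratic sub-sample refinement of peak times.
#' @return Numeric vector of peak times (possibly empty), with attributes
#'   `index` (sample index of each peak) and `height`.
#' @export
detect_peaks <- function(series, min_prominence = 0.1, refine = TRUE) {
  s <- as_series(series)
  t <- s$time; x <- s$value
  n <- length(t)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  rng <- max(x) - min(x)
  empty <- structure(numeric(0), index = integer(0), height = numeric(0))
  if (rng == 0) return(empty)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) {
    xi <- x[i]
    j <- i - 1L; lmin <- x[j]
    while (j >= 1L && x[j] <= xi) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1L }
    k <- i + 1L; rmin <- x[k]
    while (k <= n && x[k] <= xi) { if (x[k] < rmin) rmin <- x[k]; k <- k + 1L }
    xi - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence * rng
  idx <- cand[keep]
  if (!length(idx)) return(empty)
  times <- t[idx]
  if (refine) {
    for (q in seq_along(idx)) {
      i <- idx[q]
      if (x[i] == x[i + 1L]) next # plateau: keep the earlier sample
      tt <- t[(i - 1L):(i + 1L)]; xx <- x[(i - 1L):(i + 1L)]
      # vertex of the parabola through the three points
      d21 <- (xx[2] - xx[1]) / (tt[2] - tt[1])
      d32 <- (xx[3] - xx[2]) / (tt[3] - tt[2])
      a <- (d32 - d21) / (tt[3] - tt[1])
      if (a < 0) {
        v <- (tt[1] + tt[2]) / 2 - d21 / (2 * a)
        if (v >= tt[1] && v <= tt[3]) times[q] <- v
      }
    }
  }
  structure(times, index = idx, height = x[idx])
}

as_series <- function(series) {
  if (!is.data.frame(series) || ncol(series) < 2L)
    stop("series must be a data.frame with (time, value) columns",
         call. = FALSE)
  t <- as.numeric(series[[1]]); x <- as.numeric(series[[2]])
  if (any(!is.finite(t)) || is.unsorted(t, strictly = TRUE))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  data.frame(time = t, value = x)
}

#' Schuster periodogram over a period band
#'
#' Mean-removed power at a grid of candidate periods, used as the spectral
#' cross-check for the peak-to-peak period and for the free-running-band
#' test. Long series are thinned to at most `max_samples` points before the
#' scan (the model trajectories are smooth well below the 0.5 h short-period
#' limit of the band).
#'
#' @inheritParams detect_peaks
#' @param period_range shortest and longest candidate period (h).
#' @param resolution spacing of the candidate period grid (h).
#' @param max_samples thinning cap on the number of samples used.
#' @return List with `period` (dominant period), `peak_power`,
#'   `median_power`, `peak_ratio` (`peak_power / median_power`) and the full
#'   `periods` / `power` vectors.
#' @export
spectral_period <- function(series, period_range = c(0.5, 48),
                            resolution = 0.02, max_samples = 1200) {
  s <- as_series(series)
  if (nrow(s) > max_samples) {
    pick <- unique(round(seq(1, nrow(s), length.out = max_samples)))
    s <- s[pick, ]
  }
  periods <- seq(period_range[1], period_range[2], by = resolution)
  pw <- periodogram_cpp(s$time, s$value, periods)
  i <- which.max(pw)
  list(period = periods[i], peak_power = pw[i], median_power = median(pw),
       peak_ratio = power_ratio(pw[i], median(pw)),
       periods = periods, power = pw)
}

#' Peak-to-peak period estimation with spectral cross-check
#'
#' Discards the first `discard` hours, detects peaks, and reports the mean
#' and SD of successive peak-to-peak intervals together with the dominant
#' periodogram period over 0.5-48 h. With fewer than 3 peaks after the
#' discard the peak-based period is undefined (`defined = FALSE`); the
#' spectral estimate is still reported.
#'
#' @inheritParams detect_peaks
#' @param discard initial span to drop (h, measured from the first sample).
#' @return An object of class `period_estimate`: list with `mean`, `sd`,
#'   `n_intervals`, `spectral` (dominant periodogram period, h),
#'   `spectral_ratio` (its power over the median power) and `defined`.
#' @export
estimate_period <- function(series, discard = 0, min_prominence = 0.1) {
  s <- as_series(series)
  s <- s[s$time >= s$time[1] + discard, ]
  if (nrow(s) < 3L)
    stop("fewer than 3 samples remain after discarding ", discard, " h",
         call. = FALSE)
  sp <- spectral_period(s)
  pk <- detect_peaks(s, min_prominence = min_prominence)
  if (length(pk) < 3L) {
    out <- list(mean = NA_real_, sd = NA_real_, n_intervals = 0L,
                spectral = sp$period, spectral_ratio = sp$peak_ratio,
                defined = FALSE)
  } else {
    iv <- diff(as.numeric(pk))
    out <- list(mean = mean(iv), sd = if (length(iv) > 1) sd(iv) else 0,
                n_intervals = length(iv), spectral = sp$period,
                spectral_ratio = sp$peak_ratio, defined = TRUE)
  }
  structure(out, class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("period %.3f +/- %.3f h (%d intervals); spectral %.2f h\n",
                x$mean, x$sd, x$n_intervals, x$spectral))
  else
    cat(sprintf("period undefined (<3 peaks); spectral %.2f h\n", x$spectral))
  invisible(x)
}

# default transient policy: first 96 h or 5 forcing cycles, whichever longer
default_discard <- function(protocol) {
  T <- protocol_period(protocol)
  if (is.na(T)) 96 else max(96, 5 * T)
}

#' Per-cycle phase angles
#'
#' For each complete forcing cycle after the transient, the offset (h) from
#' lights-on (the cycle start) to the chosen reference event within that
#' cycle: the tallest detected peak, the deepest trough, or the onset
#' (first upward crossing of the cycle's mid-range). Cycles without the
#' event are dropped.
#'
#' @inheritParams detect_peaks
#' @param protocol a periodic `ld_protocol` (phase angle is undefined under
#'   constant conditions).
#' @param reference `"peak"`, `"trough"`, `"onset"`, or `"fundamental"` —
#'   the peak time of the cycle's fundamental Fourier component (the
#'   least-squares sinusoid at frequency 1/T), a robust surrogate for the
#'   raw peak on sparsely sampled noisy series such as 3-hourly
#'   densitometry.
#' @param discard transient to drop (h); default 96 h or 5 cycles,
#'   whichever is longer.
#' @return Numeric vector of per-cycle offsets in `[0, T)`.
#' @export
phase_angle <- function(series, protocol, reference = c("peak", "trough",
                                                        "onset",
                                                        "fundamental"),
                        discard = NULL, min_prominence = 0.1) {
  stopifnot(inherits(protocol, "ld_protocol"))
  if (!protocol$periodic)
    stop("phase angle is undefined for non-periodic protocols (DD/LL)",
         call. = FALSE)
  reference <- match.arg(reference)
  s <- as_series(series)
  T <- protocol_period(protocol)
  if (is.null(discard)) discard <- default_discard(protocol)
  t_lo <- s$time[1] + discard
  k0 <- ceiling((t_lo - protocol$t0) / T)
  starts <- protocol$t0 + T * seq(k0, floor((max(s$time) - protocol$t0) / T) - 1)
  starts <- starts[starts >= t_lo - 1e-9]
  if (length(starts) < 3L)
    stop("need at least 3 complete cycles after the transient; have ",
         length(starts), call. = FALSE)
  w <- s[s$time >= t_lo, ]
  if (reference %in% c("peak", "trough")) {
    v <- if (reference == "trough") -w$value else w$value
    pk <- detect_peaks(data.frame(time = w$time, value = v),
                       min_prominence = min_prominence)
    ht <- attr(pk, "height")
    off <- vapply(starts, function(s0) {
      in_cyc <- which(pk >= s0 & pk < s0 + T)
      if (!length(in_cyc)) return(NA_real_)
      pk[in_cyc[which.max(ht[in_cyc])]] - s0
    }, numeric(1))
  } else if (reference == "fundamental") {
    off <- vapply(starts, function(s0) {
      i <- which(w$time >= s0 & w$time < s0 + T)
      if (length(i) < 3L) return(NA_real_)
      x <- w$value[i] - mean(w$value[i])
      ang <- 2 * pi * (w$time[i] - s0) / T
      z <- sum(x * exp(-1i * ang))
      if (Mod(z) == 0) return(NA_real_)
      (-Arg(z) * T / (2 * pi)) %% T
    }, numeric(1))
  } else {
    off <- vapply(starts, function(s0) {
      i <- which(w$time >= s0 & w$time < s0 + T)
      if (length(i) < 3L) return(NA_real_)
      mid <- (max(w$value[i]) + min(w$value[i])) / 2
      up <- which(w$value[i][-length(i)] < mid & w$value[i][-1] >= mid)
      if (!length(up)) return(NA_real_)
      j <- i[up[1]]
      t_cross <- w$time[j] + (mid - w$value[j]) *
        (w$time[j + 1] - w$time[j]) / (w$value[j + 1] - w$value[j])
      t_cross - s0
    }, numeric(1))
  }
  off[!is.na(off)]
}

power_ratio <- function(peak, med) {
  if (med > 0) peak / med else if (peak > 0) Inf else 0
}

# SD of cyclic offsets in [0, T): deviations measured around the circular
# mean so that jitter across the cycle boundary does not inflate the SD
circular_sd <- function(off, T) {
  if (length(off) < 2L) return(0)
  ang <- off * 2 * pi / T
  mu <- atan2(mean(sin(ang)), mean(cos(ang)))
  dev <- ((ang - mu + pi) %% (2 * pi) - pi) * T / (2 * pi)
  sqrt(mean(dev^2))
}

#' Rhythm report and entrainment classification
#'
#' Quantifies a series against a protocol and classifies it as `entrained`,
#' `free_running` or `arrhythmic`, following the operational definition of
#' entrainment: a rhythm whose period equals the cycle length with a stable
#' phase angle, regardless of whether the internal oscillator is
#' synchronized. Specifically, the series is `entrained` iff (i) the mean
#' peak-to-peak period of the per-cycle fundamental component matches T
#' within `period_tol` (relative), (ii) the phase-angle SD (circular, on
#' the `"fundamental"` reference, robust on sparse noisy series) is at most
#' `max(0.5 h, 0.1 T)`, and (iii) the power at 1/T is at least the
#' strongest circadian-band power away from T's 5% neighborhood, so a
#' small phase-locked saw-tooth riding on a dominant free run cannot pass
#' as entrainment. Otherwise the series is `free_running` if the
#' periodogram has a dominant period inside `fr_band` (default 16-32 h,
#' bracketing the ~22 h endogenous period) with peak power at least
#' `fr_power_ratio` times the median periodogram power; otherwise
#' `arrhythmic`. A flat post-transient series is `arrhythmic` outright.
#'
#' @inheritParams phase_angle
#' @param protocol an `ld_protocol`; for non-periodic protocols only the
#'   free-running/arrhythmic distinction applies.
#' @param period_tol relative tolerance on the period match.
#' @param phase_sd_max phase-angle SD threshold (h); default
#'   `max(0.5, 0.1 * T)`.
#' @param fr_band free-running period band (h).
#' @param fr_power_ratio periodogram peak-to-median power required to call a
#'   free run.
#' @return `rhythm_report`: an object of class `rhythm_report` with fields
#'   `period_peaks` (mean), `period_sd`, `period_spectral`, `phase_angles`,
#'   `phase_sd`, `classification` and `forcing_band_power_ratio`.
#'   `classify_entrainment`: the classification string alone.
#' @export
rhythm_report <- function(series, protocol, period_tol = 0.05,
                          phase_sd_max = NULL, discard = NULL,
                          min_prominence = 0.1, fr_band = c(16, 32),
                          fr_power_ratio = 3) {
  stopifnot(inherits(protocol, "ld_protocol"))
  s <- as_series(series)
  if (is.null(discard)) discard <- default_discard(protocol)
  T <- protocol_period(protocol)
  span <- max(s$time) - (s$time[1] + discard)
  if (!is.na(T)) {
    if (span < 10 * T)
      stop("insufficient data: need >= ", 10 * T, " h (10 cycles) after the ",
           discard, " h transient, have ", round(span, 1), " h",
           call. = FALSE)
  } else if (span < 2 * fr_band[2]) {
    stop("insufficient data: need >= ", 2 * fr_band[2],
         " h after the transient to assess a free run", call. = FALSE)
  }
  pe <- estimate_period(s, discard = discard, min_prominence = min_prominence)
  w <- s[s$time >= s$time[1] + discard, ]
  # a flat post-transient series (e.g. a silenced knockout) is arrhythmic;
  # power ratios of numerical noise must not masquerade as a free run
  flat <- diff(range(w$value)) < 1e-6 * max(1, abs(mean(w$value)))
  sp <- spectral_period(w)
  in_band <- sp$periods >= fr_band[1] & sp$periods <= fr_band[2]
  band_ratio <- power_ratio(max(sp$power[in_band]), sp$median_power)
  if (flat) band_ratio <- 0
  band_period <- sp$periods[in_band][which.max(sp$power[in_band])]
  # strongest circadian-band power away from the forcing period itself:
  # an entrained series must not hide a dominant free-running component
  excl <- in_band & abs(sp$periods - ifelse(is.na(T), -1, T)) > 0.05 *
    ifelse(is.na(T), 1, T)
  band_power_excl <- if (any(excl)) max(sp$power[excl]) else 0
  if (!is.na(T)) {
    forcing_power <- periodogram_cpp(w$time, w$value, T)
    forcing_ratio <- power_ratio(forcing_power, sp$median_power)
    # per-cycle phases of the fundamental at 1/T: robust on sparse noisy
    # series, and their unwrapped peak times give the period of the
    # cycle-tracking component
    ph <- tryCatch(phase_angle(s, protocol, "fundamental",
                               discard = discard),
                   error = function(e) numeric(0))
    ph_sd <- if (length(ph) >= 3) circular_sd(ph, T) else NA_real_
    per_fund <- NA_real_; per_fund_sd <- NA_real_
    if (length(ph) >= 3) {
      ang <- ph * 2 * pi / T
      mu <- atan2(mean(sin(ang)), mean(cos(ang)))
      dev <- ((ang - mu + pi) %% (2 * pi) - pi) * T / (2 * pi)
      iv <- T + diff(dev)
      per_fund <- mean(iv); per_fund_sd <- sd(iv)
    }
    if (is.null(phase_sd_max)) phase_sd_max <- max(0.5, 0.1 * T)
    # the classification (and the reported peak period) follow the
    # fundamental-based estimate when enough cycles support it
    if (is.finite(per_fund)) { pe$mean <- per_fund; pe$sd <- per_fund_sd
                               pe$defined <- TRUE }
    entrained <- !flat && pe$defined && is.finite(pe$mean) &&
      abs(pe$mean - T) / T <= period_tol &&
      !is.na(ph_sd) && ph_sd <= phase_sd_max &&
      forcing_power >= band_power_excl
    cls <- if (entrained) "entrained"
    else if (band_ratio >= fr_power_ratio) "free_running"
    else "arrhythmic"
  } else {
    forcing_ratio <- NA_real_
    ph <- numeric(0); ph_sd <- NA_real_
    cls <- if (band_ratio >= fr_power_ratio) "free_running" else "arrhythmic"
  }
  structure(list(period_peaks = pe$mean, period_sd = pe$sd,
                 period_spectral = pe$spectral,
                 free_running_period = band_period,
                 free_running_band_ratio = band_ratio,
                 phase_angles = ph, phase_sd = ph_sd,
                 classification = cls,
                 forcing_band_power_ratio = as.numeric(forcing_ratio)),
            class = "rhythm_report")
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat("<rhythm_report> classification:", x$classification, "\n")
  cat(sprintf("  period (peaks) %.3f +/- %.3f h; spectral %.2f h\n",
              x$period_peaks, x$period_sd, x$period_spectral))
  if (length(x$phase_angles))
    cat(sprintf("  phase angle SD %.3f h over %d cycles\n", x$phase_sd,
                length(x$phase_angles)))
  invisible(x)
}

#' @rdname rhythm_report
#' @param ... passed on to [rhythm_report()].
#' @export
classify_entrainment <- function(series, protocol, ...) {
  rhythm_report(series, protocol, ...)$classification
}

#' Serialize a rhythm report to JSON
#'
#' @param x a `rhythm_report`.
#' @param path optional file to write to.
#' @return The JSON string.
#' @export
report_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "rhythm_report"))
  txt <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, na = "null")
  if (!is.null(path)) writeLines(txt, path)
  as.character(txt)
}

#' Mean per-cycle light-induced induction
#'
#' For each complete post-transient forcing cycle: the maximum of the series
#' during the light phase minus its value at lights-on, averaged over
#' cycles. This is the direct transcriptional response to the light stimulus
#' whose decline at shorter cycle lengths reflects photoadaptation.
#'
#' @inheritParams phase_angle
#' @return Mean per-cycle induction (a.u.).
#' @export
light_response_amplitude <- function(series, protocol, discard = NULL) {
  stopifnot(inherits(protocol, "ld_protocol"))
  if (!protocol$periodic || all(protocol$intensities == 0) ||
      all(protocol$intensities > 0))
    stop("protocol must be periodic with both a light and a dark phase",
         call. = FALSE)
  s <- as_series(series)
  T <- protocol_period(protocol)
  if (is.null(discard)) discard <- default_discard(protocol)
  light_i <- which(protocol$intensities > 0)[1]
  o_L <- c(0, cumsum(protocol$durations))[light_i]
  d_L <- protocol$durations[light_i]
  t_lo <- s$time[1] + discard
  k0 <- ceiling((t_lo - protocol$t0 - o_L) / T)
  ons <- protocol$t0 + o_L + T * k0:floor((max(s$time) - protocol$t0 - o_L -
                                             d_L) / T)
  ons <- ons[ons >= t_lo - 1e-9]
  if (length(ons) < 3L)
    stop("need at least 3 complete cycles after the transient", call. = FALSE)
  amp <- vapply(ons, function(on) {
    i <- which(s$time >= on & s$time <= on + d_L)
    if (length(i) < 2L) return(NA_real_)
    v0 <- interp_at(s, on)
    max(s$value[i]) - v0
  }, numeric(1))
  mean(amp, na.rm = TRUE)
}

interp_at <- function(s, t) {
  stats::approx(s$time, s$value, xout = t, rule = 2)$y
}

#' Protein/mRNA smoothing ratio at the forcing frequency
#'
#' Power of the protein series at the forcing frequency 1/T divided by the
#' power of the mRNA series at 1/T, each normalized by its series variance
#' over the post-transient window (truncated to an integer number of
#' cycles). A ratio below 1 means the protein tracks the light cycle less
#' than the mRNA does: the delayed synthesis stage acts as a low-pass
#' filter, so high-frequency light signatures present in the mRNA are
#' attenuated in the protein.
#'
#' @param protein_series,mrna_series series on the identical time grid.
#' @inheritParams phase_angle
#' @return Dimensionless ratio.
#' @export
smoothness_ratio <- function(protein_series, mrna_series, protocol,
                             discard = NULL) {
  stopifnot(inherits(protocol, "ld_protocol"))
  if (!protocol$periodic)
    stop("smoothness ratio requires a periodic protocol", call. = FALSE)
  p <- as_series(protein_series); m <- as_series(mrna_series)
  if (nrow(p) != nrow(m) || any(abs(p$time - m$time) > 1e-9))
    stop("protein and mRNA series must share the same time grid",
         call. = FALSE)
  T <- protocol_period(protocol)
  if (is.null(discard)) discard <- default_discard(protocol)
  t_lo <- p$time[1] + discard
  n_cyc <- floor((max(p$time) - t_lo) / T)
  if (n_cyc < 3L)
    stop("need at least 3 complete cycles after the transient", call. = FALSE)
  keep <- p$time >= t_lo & p$time < t_lo + n_cyc * T
  band_power <- function(s) {
    pw <- periodogram_cpp(s$time[keep], s$value[keep], T)
    v <- var(s$value[keep])
    if (v == 0) return(NA_real_)
    pw / v
  }
  band_power(p) / band_power(m)
}
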