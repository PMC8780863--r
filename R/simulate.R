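#' Integrate the delayed clock model under a light protocol
#'
#' Fixed-step 4th-order (classical Runge-Kutta) method-of-steps integration
#' of the six-variable delay system, with cubic Lagrange interpolation for
#' the delayed \emph{frq} mRNA lookup and a constant pre-zero history. The
#' step size is refined, if needed, so that every light transition falls
#' exactly on a grid point: light forcing is discontinuous, and aligning
#' steps to the transitions removes the discontinuity error that an adaptive
#' stepper would otherwise have to chase. The result is deterministic for
#' identical inputs.
#'
#' @param params a `clock_parameters` object.
#' @param protocol an `ld_protocol`.
#' @param t_end end time (h); the grid extends to the smallest aligned step
#'   multiple that is >= `t_end`.
#' @param dt requested step size (h); must satisfy `dt <= tau / 20`. The
#'   effective step actually used (possibly smaller, to align transitions)
#'   is stored in the result.
#' @param history constant history state (components >= 0) held for all
#'   t <= 0; also the initial state.
#' @return An object of class `clock_trajectory`: list with `times` (uniform
#'   grid from 0), `states` (matrix with columns `M_frq`, `F`, `M_wc1`,
#'   `W_dark`, `W_light`, `V`), `light` (per-step forcing level), `dt`,
#'   `params` and `protocol` (enough metadata to re-run exactly).
#' @examples
#' \donttest{
#' traj <- simulate_clock(default_parameters(), symmetric_ld(6), 240)
#' head(as.data.frame(traj))
#' }
#' @export
simulate_clock <- function(params, protocol, t_end, dt = 0.01,
                           history = rep(0.1, 6)) {
  stopifnot(inherits(params, "clock_parameters"),
            inherits(protocol, "ld_protocol"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0",
                                            call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (dt > params$tau / 20 + 1e-12)
    stop("dt = ", dt, " too large for delay tau = ", params$tau,
         "; use dt <= tau/20 = ", params$tau / 20,
         " so the delayed lookup stays well-resolved", call. = FALSE)
  history <- as.numeric(history)
  if (length(history) != 6L || any(!is.finite(history)) || any(history < 0))
    stop("history must be 6 nonnegative finite values", call. = FALSE)
  dt_eff <- aligned_dt(protocol, dt)
  n <- ceiling(t_end / dt_eff - 1e-9)
  times <- seq(0, by = dt_eff, length.out = n + 1)
  light <- light_at(protocol, times[-(n + 1)])
  states <- dde_integrate_cpp(unname(param_vector(params)), light, dt_eff,
                              history)
  colnames(states) <- c("M_frq", "F", "M_wc1", "W_dark", "W_light", "V")
  structure(list(times = times, states = states,
                 light = c(light, light_at(protocol, times[n + 1])),
                 dt = dt_eff, params = params, protocol = protocol,
                 history = history),
            class = "clock_trajectory")
}

# largest step <= dt that divides every phase duration (and t0 offset), so
# that all transitions land on grid points; durations are resolved to whole
# seconds
aligned_dt <- function(protocol, dt) {
  if (!protocol$periodic && length(protocol$durations) == 1L) return(dt)
  durs <- protocol$durations
  if (protocol$t0 != 0) durs <- c(durs, abs(protocol$t0))
  secs <- durs * 3600
  if (any(abs(secs - round(secs)) > 1e-6))
    stop("phase durations must be whole numbers of seconds to align the ",
         "integration grid to light transitions", call. = FALSE)
  g <- Reduce(function(a, b) {
    while (b > 0) { r <- a %% b; a <- b; b <- r }
    a
  }, round(secs)) / 3600
  g / ceiling(g / dt - 1e-9)
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat("<clock_trajectory> ", length(x$times), " points, t in [0, ",
      max(x$times), "] h, dt = ", x$dt, " h\n", sep = "")
  cat("protocol: ", protocol_label(x$protocol), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.clock_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, x$states, light = x$light)
}

#' Extract one state component as a time series
#'
#' @param traj a `clock_trajectory`.
#' @param component one of `"M_frq"`, `"F"`, `"M_wc1"`, `"W_dark"`,
#'   `"W_light"`, `"V"`.
#' @return A two-column data.frame (`time`, `value`), the series format the
#'   rhythm-analysis functions consume.
#' @export
trajectory_series <- function(traj, component = "F") {
  stopifnot(inherits(traj, "clock_trajectory"))
  component <- match.arg(component, colnames(traj$states))
  data.frame(time = traj$times, value = traj$states[, component])
}

#' Trajectory CSV export / series import
#'
#' Trajectories export with columns `time_h`, the six state variables and
#' `light`. `read_series_csv` reads any 2+-column CSV whose first two
#' columns are time (h) and value.
#'
#' @param traj a `clock_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory_csv`: the path, invisibly;
#'   `read_series_csv`: a (`time`, `value`) data.frame.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_series_csv <- function(path) {
  d <- read.csv(path)
  if (ncol(d) < 2L) stop("need at least two columns (time, value)",
                         call. = FALSE)
  out <- data.frame(time = as.numeric(d[[1]]), value = as.numeric(d[[2]]))
  if (any(!is.finite(out$time)) || is.unsorted(out$time, strictly = TRUE))
    stop("time column must be finite and strictly increasing", call. = FALSE)
  out
}
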