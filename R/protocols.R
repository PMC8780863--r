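#' Piecewise-constant light-dark protocols
#'
#' An `ld_protocol` is an ordered list of phases, each a duration (h) and a
#' light intensity in \[0, 1\] (intensity 1.0 maps to 5000 lux, 0.2 to
#' 1000 lux). Periodic protocols repeat the phase list with cycle length
#' `T = sum(durations)`; `t0` is the time of first lights-on, so a
#' simulation started at t = 0 with the default `t0 = 0` begins at
#' lights-on, the universal phase reference used throughout the package.
#'
#' @param phases a two-column matrix or data.frame (duration_h, intensity),
#'   or a list of length-2 vectors.
#' @param periodic logical; if `TRUE` the phases repeat indefinitely.
#' @param t0 time of the start of the first phase (h).
#' @return An object of class `ld_protocol`.
#' @seealso [symmetric_ld()], [asymmetric_ld()], [ld_constant()],
#'   [light_at()], [parse_protocol()]
#' @export
ld_protocol <- function(phases, periodic = TRUE, t0 = 0) {
  if (is.list(phases) && !is.data.frame(phases))
    phases <- do.call(rbind, phases)
  phases <- as.matrix(phases)
  if (ncol(phases) != 2L || nrow(phases) < 1L)
    stop("phases must be rows of (duration_h, intensity)", call. = FALSE)
  dur <- as.numeric(phases[, 1]); int <- as.numeric(phases[, 2])
  if (any(!is.finite(dur)) || any(dur <= 0))
    stop("all phase durations must be positive and finite", call. = FALSE)
  if (any(!is.finite(int)) || any(int < 0) || any(int > 1))
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (!is.finite(t0)) stop("t0 must be finite", call. = FALSE)
  structure(list(durations = dur, intensities = int,
                 periodic = isTRUE(periodic), t0 = t0),
            class = "ld_protocol")
}

#' @export
print.ld_protocol <- function(x, ...) {
  lab <- protocol_label(x)
  cat("<ld_protocol> ", lab, "\n", sep = "")
  if (x$periodic) cat("cycle length T =", protocol_period(x), "h\n")
  invisible(x)
}

protocol_label <- function(p) {
  if (!p$periodic && length(p$durations) == 1L) {
    if (p$intensities[1] == 0) return("DD (constant darkness)")
    if (p$intensities[1] == 1) return("LL (constant light)")
    return(sprintf("constant light %.2f", p$intensities[1]))
  }
  paste(sprintf("%.3gh@%.2g", p$durations, p$intensities), collapse = " | ")
}

#' Symmetric light-dark cycle
#'
#' Equal light and dark phases (LDx:x); cycle length `T = 2 * half_period`.
#'
#' @param half_period duration of each phase (h).
#' @param intensity light intensity in \[0, 1\].
#' @return An `ld_protocol` (light then dark, periodic).
#' @examples
#' symmetric_ld(3)          # LD3:3, T = 6 h
#' symmetric_ld(0.75)       # LD45min:45min, T = 1.5 h
#' @export
symmetric_ld <- function(half_period, intensity = 1.0) {
  if (!is.finite(half_period) || half_period <= 0)
    stop("half_period must be positive", call. = FALSE)
  ld_protocol(rbind(c(half_period, intensity), c(half_period, 0)))
}

#' Asymmetric light-dark cycle
#'
#' Unequal light and dark phases, e.g. the 90-min orbital-flight regime
#' LD65min:25min, `asymmetric_ld(65/60, 25/60)`.
#'
#' @param light_h,dark_h phase durations (h).
#' @inheritParams symmetric_ld
#' @return An `ld_protocol` (light then dark, periodic).
#' @export
asymmetric_ld <- function(light_h, dark_h, intensity = 1.0) {
  if (!is.finite(light_h) || light_h <= 0 || !is.finite(dark_h) || dark_h <= 0)
    stop("both phase durations must be positive", call. = FALSE)
  ld_protocol(rbind(c(light_h, intensity), c(dark_h, 0)))
}

#' Constant-light protocol
#'
#' Non-periodic single-phase protocol: `ld_constant(0)` is constant darkness
#' (DD), `ld_constant(1)` constant light (LL) at 5000 lux, `ld_constant(0.2)`
#' constant 1000 lux.
#'
#' @inheritParams symmetric_ld
#' @return A non-periodic `ld_protocol`.
#' @export
ld_constant <- function(intensity) {
  if (!is.finite(intensity) || intensity < 0 || intensity > 1)
    stop("intensity must lie in [0, 1]", call. = FALSE)
  # duration is nominal; a non-periodic protocol holds its last phase forever
  ld_protocol(rbind(c(1, intensity)), periodic = FALSE)
}

#' Cycle length of a periodic protocol
#'
#' @param p an `ld_protocol`.
#' @return Cycle length T (h), or `NA` for non-periodic protocols.
#' @export
protocol_period <- function(p) {
  stopifnot(inherits(p, "ld_protocol"))
  if (!p$periodic) return(NA_real_)
  sum(p$durations)
}

#' Evaluate a protocol at given times
#'
#' Piecewise-constant, right-continuous evaluation: a transition time belongs
#' to the phase it begins, so `light_at(symmetric_ld(6), 6)` is 0 (the dark
#' phase has just started). Non-periodic protocols hold their last phase for
#' all later times and their first phase for earlier times.
#'
#' @param p an `ld_protocol`.
#' @param t time or vector of times (h).
#' @return Numeric vector of light intensities in \[0, 1\].
#' @export
light_at <- function(p, t) {
  stopifnot(inherits(p, "ld_protocol"))
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  rel <- t - p$t0
  ends <- cumsum(p$durations)
  total <- ends[length(ends)]
  if (p$periodic) {
    rel <- rel %% total
    idx <- findInterval(rel, c(0, ends), rightmost.closed = FALSE,
                        left.open = FALSE)
    idx[idx > length(p$durations)] <- length(p$durations)
  } else {
    idx <- findInterval(rel, c(0, ends))
    idx[idx < 1L] <- 1L
    idx[idx > length(p$durations)] <- length(p$durations)
  }
  p$intensities[idx]
}

#' Parse protocol shorthand
#'
#' Accepts `"DD"`, `"LL"`, `"LDx:y"` with durations in hours, or minutes
#' with an `m` suffix, e.g. `"LD6:6"`, `"LD65m:25m"`, `"LD45m:45m"`.
#'
#' @param text shorthand string.
#' @inheritParams symmetric_ld
#' @return An `ld_protocol`.
#' @export
parse_protocol <- function(text, intensity = 1.0) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (toupper(s) == "DD") return(ld_constant(0))
  if (toupper(s) == "LL") return(ld_constant(intensity))
  m <- regmatches(s, regexec("^LD\\s*([0-9.]+)(m?)\\s*:\\s*([0-9.]+)(m?)$",
                             s, ignore.case = TRUE))[[1]]
  if (length(m) == 0)
    stop("cannot parse protocol '", text,
         "'; expected DD, LL or LDx:y (m suffix for minutes)", call. = FALSE)
  a <- as.numeric(m[2]) / ifelse(nzchar(m[3]), 60, 1)
  b <- as.numeric(m[4]) / ifelse(nzchar(m[5]), 60, 1)
  asymmetric_ld(a, b, intensity)
}

#' Serialize / deserialize protocols
#'
#' Protocols are exchanged as
#' `{"phases": [[duration_h, intensity], ...], "periodic": bool, "t0": h}`.
#'
#' @param p an `ld_protocol`.
#' @param path file to write to; if `NULL` the JSON text is returned.
#' @return `protocol_to_json`: JSON string; `protocol_from_json`: an
#'   `ld_protocol`.
#' @export
protocol_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "ld_protocol"))
  obj <- list(phases = unname(cbind(p$durations, p$intensities)),
              periodic = p$periodic, t0 = p$t0)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' @param x a file path or a JSON string.
#' @rdname protocol_to_json
#' @export
protocol_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  ld_protocol(obj$phases, periodic = obj$periodic, t0 = obj$t0)
}
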