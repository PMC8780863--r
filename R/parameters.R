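#' Model parameters for the delayed FRQ/WCC/VVD oscillator
#'
#' Constructs and validates the full parameter set of the six-variable delay
#' differential model of the Neurospora core clock. The state variables are
#' cytosolic \emph{frq} mRNA (`M_frq`), nuclear FRQ protein (`F`),
#' \emph{wc-1} mRNA (`M_wc1`), phosphorylated dark-state nuclear WCC
#' (`W_dark`), light-activated WCC (`W_light`) and the photoadaptation
#' protein VVD (`V`). Time is in hours, concentrations in arbitrary units;
#' light intensity is normalized so that 5000 lux corresponds to 1.0 and
#' 1000 lux to 0.2.
#'
#' FRQ synthesis is proportional to \emph{frq} mRNA a delay `tau` hours
#' earlier, lumping translation, progressive phosphorylation and nuclear
#' translocation into a single lag of several hours, so `tau` is constrained
#' to \[2, 8\] h.
#'
#' @param v_dark,v_light frq transcription rates driven by dark-state and
#'   light-activated WCC (a.u./h).
#' @param K_I FRQ repression half-constant (a.u.).
#' @param h repression Hill exponent (>= 1).
#' @param d_M frq mRNA degradation rate (1/h).
#' @param k_s FRQ synthesis rate per unit delayed mRNA (1/h).
#' @param tau lumped translation/phosphorylation/translocation delay (h),
#'   in \[2, 8\].
#' @param d_F FRQ clearance rate (FWD-1 pathway proxy, 1/h).
#' @param v_w basal wc-1 transcription (a.u./h).
#' @param k_fw FRQ support of wc-1 transcription (1/h); set to 0 to remove
#'   the positive limb.
#' @param d_Mw wc-1 mRNA degradation (1/h).
#' @param k_w WCC production per wc-1 mRNA (1/h).
#' @param d_Wd,d_Wl clearance rates of the dark and light WCC states (1/h).
#' @param k_act light activation rate of WCC (1/h per unit light).
#' @param k_rel reversion rate of light-activated WCC to the dark state (1/h).
#' @param K_V VVD inhibition half-constant (a.u.).
#' @param k_v VVD induction rate per light-activated WCC (1/h).
#' @param d_V VVD clearance (1/h).
#' @param frq_null,wc_null,vvd_null knockout switches zeroing, respectively,
#'   FRQ synthesis (`k_s`), WCC production (`k_w`) and VVD induction (`k_v`).
#' @return An object of class `clock_parameters` (a validated named list).
#' @seealso [default_parameters()], [apply_knockout()], [clock_derivative()]
#' @export
model_parameters <- function(v_dark, v_light, K_I, h, d_M, k_s, tau, d_F,
                             v_w, k_fw, d_Mw, k_w, d_Wd, d_Wl,
                             k_act, k_rel, K_V, k_v, d_V,
                             frq_null = FALSE, wc_null = FALSE,
                             vvd_null = FALSE) {
  p <- list(v_dark = v_dark, v_light = v_light, K_I = K_I, h = h, d_M = d_M,
            k_s = k_s, tau = tau, d_F = d_F, v_w = v_w, k_fw = k_fw,
            d_Mw = d_Mw, k_w = k_w, d_Wd = d_Wd, d_Wl = d_Wl,
            k_act = k_act, k_rel = k_rel, K_V = K_V, k_v = k_v, d_V = d_V,
            frq_null = isTRUE(frq_null), wc_null = isTRUE(wc_null),
            vvd_null = isTRUE(vvd_null))
  validate_parameters(p)
}

.param_numeric_fields <- c("v_dark", "v_light", "K_I", "h", "d_M", "k_s",
                           "tau", "d_F", "v_w", "k_fw", "d_Mw", "k_w",
                           "d_Wd", "d_Wl", "k_act", "k_rel", "K_V", "k_v",
                           "d_V")
.param_flag_fields <- c("frq_null", "wc_null", "vvd_null")

validate_parameters <- function(p) {
  for (f in .param_numeric_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("negative parameter '", f, "': rates and half-constants must be ",
           ">= 0", call. = FALSE)
  }
  # strict positivity except where a knockout flag zeroes the synthesis
  # term, and except k_fw which may legitimately be 0 (no positive limb)
  must_pos <- setdiff(.param_numeric_fields, "k_fw")
  for (f in must_pos) {
    if (p[[f]] == 0)
      stop("parameter '", f, "' must be > 0 (use the knockout flags to ",
           "silence a gene)", call. = FALSE)
  }
  if (p$h < 1) stop("Hill exponent h must be >= 1", call. = FALSE)
  if (p$tau < 2 || p$tau > 8)
    stop("delay tau must lie in [2, 8] h (a lag of several hours)",
         call. = FALSE)
  for (f in .param_flag_fields) {
    if (!is.logical(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]))
      stop("flag '", f, "' must be TRUE or FALSE", call. = FALSE)
  }
  structure(p[c(.param_numeric_fields, .param_flag_fields)],
            class = "clock_parameters")
}

#' @export
print.clock_parameters <- function(x, ...) {
  cat("<clock_parameters>\n")
  num <- unlist(x[.param_numeric_fields])
  print(round(num, 5))
  ko <- unlist(x[.param_flag_fields])
  if (any(ko)) cat("knockouts:", paste(names(ko)[ko], collapse = ", "), "\n")
  invisible(x)
}

# effective rate vector for the integrator/derivative, with knockout flags
# folded into the synthesis rates
param_vector <- function(p) {
  stopifnot(inherits(p, "clock_parameters"))
  v <- unlist(p[.param_numeric_fields], use.names = TRUE)
  if (p$frq_null) v["k_s"] <- 0
  if (p$wc_null) v["k_w"] <- 0
  if (p$vvd_null) v["k_v"] <- 0
  v
}

#' Committed calibrated parameter set
#'
#' Returns the parameter set obtained by [calibrate_parameters()] against the
#' printed behavioral constraints (a ~22 h free-running period in constant
#' darkness, entrainment to symmetric LD cycles down to 3 h half-period,
#' free-running FRQ with saw-tooth superimposition at 2 h half-period,
#' light-response amplitude decreasing with cycle length, and protein
#' smoothing at short cycles), stored with the package as plain-text JSON.
#' Deterministic across calls.
#'
#' @return A `clock_parameters` object.
#' @examples
#' p <- default_parameters()
#' p$tau
#' @export
default_parameters <- function() {
  if (is.null(.frqclock_env$default_params)) {
    path <- system.file("extdata", "default_params.json",
                        package = "frqclock", mustWork = TRUE)
    .frqclock_env$default_params <- params_from_json(path)
  }
  .frqclock_env$default_params
}

#' Strain-like parameter modifications
#'
#' Maps the classic strains to parameter changes: `"frq"` (frq^10-like null),
#' `"wc-1"` (wc-1^RIP-like null) and `"vvd"` (vvd^KO) set the corresponding
#' knockout flag; `"frq7"` and `"frq2"` scale the FRQ clearance rate `d_F`
#' (by 0.7 and 1.4) to give free-running periods longer and shorter than the
#' wild-type ~22 h, mirroring the altered FRQ stability of those point
#' mutants.
#'
#' @param p a `clock_parameters` object.
#' @param gene one of `"frq"`, `"wc-1"`, `"vvd"`, `"frq7"`, `"frq2"`.
#' @return A modified copy of `p`; the input is untouched.
#' @export
apply_knockout <- function(p, gene) {
  stopifnot(inherits(p, "clock_parameters"))
  supported <- c("frq", "wc-1", "vvd", "frq7", "frq2")
  if (!is.character(gene) || length(gene) != 1L || !(gene %in% supported))
    stop("unknown gene label '", paste(gene, collapse = ","),
         "'; supported: ", paste(supported, collapse = ", "), call. = FALSE)
  q <- unclass(p)
  switch(gene,
         "frq"  = { q$frq_null <- TRUE },
         "wc-1" = { q$wc_null <- TRUE },
         "vvd"  = { q$vvd_null <- TRUE },
         "frq7" = { q$d_F <- q$d_F * 0.7 },
         "frq2" = { q$d_F <- q$d_F * 1.4 })
  validate_parameters(q)
}

#' Right-hand side of the delayed clock model
#'
#' Evaluates the six time-derivatives given the current state, the delayed
#' state (which supplies \emph{frq} mRNA at `t - tau`) and the current light
#' level. The equations are:
#' \deqn{dM_{frq}/dt = (v_{dark} W_{dark} + v_{light} W_{light})
#'   \frac{K_I^h}{K_I^h + F^h} - d_M M_{frq}}
#' \deqn{dF/dt = k_s M_{frq}(t-\tau) - d_F F}
#' \deqn{dM_{wc1}/dt = v_w + k_{fw} F - d_{Mw} M_{wc1}}
#' \deqn{dW_{dark}/dt = k_w M_{wc1} - k_{act} L W_{dark}/(1 + V/K_V)
#'   + k_{rel} W_{light} - d_{Wd} W_{dark}}
#' \deqn{dW_{light}/dt = k_{act} L W_{dark}/(1 + V/K_V)
#'   - k_{rel} W_{light} - d_{Wl} W_{light}}
#' \deqn{dV/dt = k_v W_{light} - d_V V}
#'
#' @param now numeric state vector of length 6
#'   (`M_frq`, `F`, `M_wc1`, `W_dark`, `W_light`, `V`).
#' @param delayed state vector of length 6 at time `t - tau`; only its
#'   `M_frq` component enters the equations.
#' @param light light level in \[0, 1\].
#' @param p a `clock_parameters` object.
#' @return Named numeric vector of the six derivatives.
#' @export
clock_derivative <- function(now, delayed, light, p) {
  stopifnot(inherits(p, "clock_parameters"))
  now <- as.numeric(now); delayed <- as.numeric(delayed)
  if (length(now) != 6L || length(delayed) != 6L)
    stop("state vectors must have length 6", call. = FALSE)
  if (!all(is.finite(now)) || !all(is.finite(delayed)))
    stop("non-finite state: integrator blow-up", call. = FALSE)
  if (any(now < 0) || any(delayed < 0))
    stop("state components must be >= 0", call. = FALSE)
  if (!is.finite(light) || light < 0 || light > 1)
    stop("light must lie in [0, 1]", call. = FALSE)
  v <- param_vector(p)
  M <- now[1]; F <- now[2]; Mw <- now[3]; Wd <- now[4]; Wl <- now[5]
  V <- now[6]
  Kh <- v["K_I"]^v["h"]
  rep_term <- Kh / (Kh + F^v["h"])
  act <- v["k_act"] * light * Wd / (1 + V / v["K_V"])
  out <- c(
    M_frq   = unname((v["v_dark"] * Wd + v["v_light"] * Wl) * rep_term -
                       v["d_M"] * M),
    F       = unname(v["k_s"] * delayed[1] - v["d_F"] * F),
    M_wc1   = unname(v["v_w"] + v["k_fw"] * F - v["d_Mw"] * Mw),
    W_dark  = unname(v["k_w"] * Mw - act + v["k_rel"] * Wl - v["d_Wd"] * Wd),
    W_light = unname(act - v["k_rel"] * Wl - v["d_Wl"] * Wl),
    V       = unname(v["k_v"] * Wl - v["d_V"] * V))
  out
}

#' Serialize / deserialize parameter sets
#'
#' Parameter sets are exchanged as a flat key-to-number JSON object with the
#' knockout flags as booleans. Unknown keys are rejected.
#'
#' @param p a `clock_parameters` object.
#' @param path file to write to; if `NULL`, the JSON text is returned.
#' @return `params_to_json`: the JSON string (invisibly if written to file);
#'   `params_from_json`: a `clock_parameters` object.
#' @export
params_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "clock_parameters"))
  txt <- jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' @param x a file path or a JSON string.
#' @rdname params_to_json
#' @export
params_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  known <- c(.param_numeric_fields, .param_flag_fields)
  extra <- setdiff(names(obj), known)
  if (length(extra))
    stop("unknown parameter keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(.param_numeric_fields, names(obj))
  if (length(missing))
    stop("missing parameter keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (f in .param_flag_fields) if (is.null(obj[[f]])) obj[[f]] <- FALSE
  validate_parameters(obj)
}
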