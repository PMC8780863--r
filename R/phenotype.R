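#' Race-tube record
#'
#' Positions (mm) of the growth front at successive 24 h marks starting at
#' inoculation (t = 0), plus the centers of the conidiation bands along the
#' tube. Band "position" is the band center. The growth marks are assumed to
#' be laid down at exact 24 h intervals.
#'
#' @param mark_positions strictly increasing positions (mm), first at the
#'   inoculation point.
#' @param band_positions strictly increasing band-center positions (mm),
#'   all within `[min(mark), max(mark)]`.
#' @param condition free-text condition label.
#' @return An object of class `race_tube_record`.
#' @export
race_tube_record <- function(mark_positions, band_positions = numeric(0),
                             condition = "") {
  m <- as.numeric(mark_positions); b <- as.numeric(band_positions)
  if (length(m) < 2L || any(!is.finite(m)) ||
      is.unsorted(m, strictly = TRUE))
    stop("mark positions must be >= 2 strictly increasing finite values",
         call. = FALSE)
  if (length(b)) {
    if (any(!is.finite(b)) || is.unsorted(b, strictly = TRUE))
      stop("band positions must be strictly increasing and finite",
           call. = FALSE)
    if (min(b) < m[1] || max(b) > m[length(m)])
      stop("bands must lie within [first mark, last mark]", call. = FALSE)
  }
  structure(list(mark_positions = m, band_positions = b,
                 condition = as.character(condition)[1]),
            class = "race_tube_record")
}

#' @export
print.race_tube_record <- function(x, ...) {
  cat("<race_tube_record>",
      if (nzchar(x$condition)) paste0("[", x$condition, "]"), "\n")
  cat("  ", length(x$mark_positions), " daily marks over ",
      diff(range(x$mark_positions)), " mm; ", length(x$band_positions),
      " bands\n", sep = "")
  invisible(x)
}

#' Convert a tube position to a growth time
#'
#' Piecewise-linear interpolation between the 24 h growth marks: between
#' marks j and j+1, `t = 24*j + 24*(position - p_j)/(p_{j+1} - p_j)` (marks
#' counted from 0 at inoculation). This converts band spacing into growth
#' time, the basis of the race-tube period read-out.
#'
#' @param record a `race_tube_record`.
#' @param position position(s) along the tube (mm), within the marked range.
#' @return Time(s) in hours.
#' @export
position_to_time <- function(record, position) {
  stopifnot(inherits(record, "race_tube_record"))
  m <- record$mark_positions
  if (any(position < m[1] - 1e-9) || any(position > m[length(m)] + 1e-9))
    stop("position outside the marked range [", m[1], ", ", m[length(m)],
         "] mm", call. = FALSE)
  stats::approx(m, 24 * (seq_along(m) - 1), xout = position)$y
}

#' Band-to-band periods of a race tube
#'
#' The period read-out: growth time between adjacent conidiation bands,
#' obtained by mapping band centers to times through the daily growth marks.
#'
#' @param record a `race_tube_record` with at least 2 bands.
#' @return List with `periods` (h), `mean`, `sd` and `defined` (FALSE with
#'   fewer than 2 bands).
#' @export
band_periods <- function(record) {
  stopifnot(inherits(record, "race_tube_record"))
  b <- record$band_positions
  if (length(b) < 2L)
    return(list(periods = numeric(0), mean = NA_real_, sd = NA_real_,
                defined = FALSE))
  tt <- position_to_time(record, b)
  per <- diff(tt)
  list(periods = per, mean = mean(per),
       sd = if (length(per) > 1) sd(per) else 0, defined = TRUE)
}

#' Daily growth and growth comparisons
#'
#' `daily_growth` returns the successive 24 h growth increments (mm/day).
#' `relative_growth` normalizes a record's mean daily growth to a reference
#' record (e.g. LD12:12). `growth_ratio` is the ratio of mean daily growth
#' of two records (e.g. frq2 over frq7).
#'
#' @param record,reference_record,record_a,record_b `race_tube_record`s.
#' @return `daily_growth`: numeric vector (mm/day); `relative_growth`:
#'   dimensionless scalar; `growth_ratio`: list with `ratio` and `defined`
#'   (FALSE when the denominator record shows no growth).
#' @export
daily_growth <- function(record) {
  stopifnot(inherits(record, "race_tube_record"))
  diff(record$mark_positions)
}

#' @rdname daily_growth
#' @export
relative_growth <- function(record, reference_record) {
  mean(daily_growth(record)) / mean(daily_growth(reference_record))
}

#' @rdname daily_growth
#' @export
growth_ratio <- function(record_a, record_b) {
  gb <- mean(daily_growth(record_b))
  if (gb <= 0) return(list(ratio = NA_real_, defined = FALSE))
  list(ratio = mean(daily_growth(record_a)) / gb, defined = TRUE)
}

#' Microconidia classification and proportion
#'
#' A conidium is counted as a microconidium iff its length/width aspect
#' ratio is strictly below 1.5 (microconidia are nearly round); the boundary
#' case of exactly 1.5 is a macroconidium. The proportion is the
#' microconidium count over the total count.
#'
#' @param length,width conidium dimensions (um), positive; vectorized.
#' @return `is_microconidium`: logical vector. `microconidia_proportion`:
#'   fraction in \[0, 1\], or `NA` for an empty measure set.
#' @export
is_microconidium <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("conidium dimensions must be positive", call. = FALSE)
  length / width < 1.5
}

#' @param measures a data.frame with columns `length_um` and `width_um`
#'   (or first two columns length, width).
#' @rdname is_microconidium
#' @export
microconidia_proportion <- function(measures) {
  if (NROW(measures) == 0L) return(NA_real_)
  len <- if ("length_um" %in% names(measures)) measures$length_um
  else measures[[1]]
  wid <- if ("width_um" %in% names(measures)) measures$width_um
  else measures[[2]]
  mean(is_microconidium(len, wid))
}

#' Correlation of a phenotype with cycle length
#'
#' Pearson correlation (with its standard t-based p-value) between LD cycle
#' lengths and a per-condition phenotype value; a rank-based alternative is
#' available via `method = "spearman"`.
#'
#' @param cycle_lengths cycle lengths T (h), one per condition (n >= 3).
#' @param values phenotype values, same length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `estimate`, `p_value`, `method` and `defined` (FALSE
#'   when either input has zero variance).
#' @export
condition_correlation <- function(cycle_lengths, values,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(cycle_lengths) != length(values) || length(values) < 3L)
    stop("need matched vectors with n >= 3", call. = FALSE)
  if (sd(cycle_lengths) == 0 || sd(values) == 0)
    return(list(estimate = NA_real_, p_value = NA_real_, method = method,
                defined = FALSE))
  ct <- cor.test(cycle_lengths, values, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method,
       defined = TRUE)
}

#' Two-sample Student's t test with significance stars
#'
#' Two-sided Student's t test (equal variances) between two groups, with the
#' conventional star labels: `*` for p <= 0.05, `**` for p <= 0.01, `***`
#' for p <= 0.001, `ns` otherwise.
#'
#' @param a,b numeric vectors (n >= 3 each).
#' @return List with `p_value`, `stars`, `estimate` (difference of means)
#'   and `t`.
#' @export
two_sample_test <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    stop("need n >= 3 per group", call. = FALSE)
  tt <- t.test(a, b, var.equal = TRUE)
  list(p_value = tt$p.value, stars = significance_stars(tt$p.value),
       estimate = unname(diff(rev(tt$estimate))), t = unname(tt$statistic))
}

#' @param p a p-value.
#' @rdname two_sample_test
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0.001) "***" else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*" else "ns"
  }, character(1))
}

#' Race-tube and morphometry CSV input/output
#'
#' The race-tube dialect is section-tagged: a `condition,<label>` header row
#' followed by `mark,<position_mm>` and `band,<position_mm>` rows.
#' Morphometry tables are plain CSV with `length_um` and `width_um` columns.
#'
#' @param record a `race_tube_record`.
#' @param path file path.
#' @return `read_race_tube`: a `race_tube_record`; `write_race_tube`: the
#'   path, invisibly; `read_morphometry`: a data.frame.
#' @export
write_race_tube <- function(record, path) {
  stopifnot(inherits(record, "race_tube_record"))
  lines <- c(paste0("condition,", record$condition),
             paste0("mark,", record$mark_positions),
             paste0("band,", record$band_positions))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_race_tube
#' @export
read_race_tube <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",")
  tags <- vapply(parts, `[`, character(1), 1)
  vals <- vapply(parts, function(p) paste(p[-1], collapse = ","),
                 character(1))
  cond <- if (any(tags == "condition")) vals[tags == "condition"][1] else ""
  race_tube_record(as.numeric(vals[tags == "mark"]),
                   as.numeric(vals[tags == "band"]), condition = cond)
}

#' @rdname write_race_tube
#' @export
read_morphometry <- function(path) {
  d <- read.csv(path)
  if (!all(c("length_um", "width_um") %in% names(d)))
    stop("morphometry CSV needs columns length_um, width_um", call. = FALSE)
  d
}
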