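# upward crossing indices of target t in sequence u: i such that
# u[i-1] < t <= u[i]
first_up_crossing <- function(u, target) {
  hits <- which(u[-1] >= target & u[-length(u)] < target) + 1L
  if (length(hits)) hits[1] else NA_integer_
}

count_crossings <- function(u, target) {
  up <- sum(u[-1] >= target & u[-length(u)] < target)
  down <- sum(u[-1] < target & u[-length(u)] >= target)
  c(up = up, down = down)
}

#' Detect quality-controlled oscillation cycles
#'
#' Delimits cycles at consecutive ascending zero-crossings of the signal
#' (unwrapped phase crossing \eqn{-\pi/2 + 2\pi k} upward) and applies three
#' quality-control checks per cycle: (i) mean instantaneous amplitude at or
#' above the `amplitude_percentile` of all cycle amplitudes in this segment,
#' (ii) unique control points (ascending zero, peak, descending zero,
#' trough, each crossed exactly once), and (iii) no phase reversal
#' (unwrapped phase strictly increasing within the cycle). Cycles touching
#' the segment boundaries (incomplete, or starting at the very first sample)
#' are discarded before QC. A cycle is accepted iff all three flags hold.
#'
#' @param attr An [instantaneous_attributes()] tibble from a single
#'   continuous segment.
#' @param amplitude_percentile Percentile (0-100) of cycle mean amplitudes
#'   below which cycles are rejected; the default keeps the top quartile.
#' @return A tibble of class `cycle_table`, one row per detected (non-edge)
#'   cycle: `cycle`, `start`, `end`, control-point sample indices
#'   (`pt_asc_zero`, `pt_peak`, `pt_desc_zero`, `pt_trough`),
#'   `mean_amplitude`, QC flags (`amplitude_ok`, `controls_ok`,
#'   `no_phase_reversal`) and `accepted`. The attribute `n_detected` records
#'   the cycle count before QC. An empty table (no complete cycle) is a
#'   value, not an error.
#' @export
detect_cycles <- function(attr, amplitude_percentile = 75) {
  stopifnot(inherits(attr, "inst_attributes"))
  check_scalar(amplitude_percentile, "amplitude_percentile", lower = 0, upper = 100)
  u <- attr$phase_unwrapped
  n <- length(u)

  k_lo <- ceiling((min(u) + pi / 2) / (2 * pi))
  k_hi <- floor((max(u) + pi / 2) / (2 * pi))
  empty <- tibble(
    cycle = integer(), start = integer(), end = integer(),
    pt_asc_zero = integer(), pt_peak = integer(), pt_desc_zero = integer(),
    pt_trough = integer(), mean_amplitude = numeric(),
    amplitude_ok = logical(), controls_ok = logical(),
    no_phase_reversal = logical(), accepted = logical()
  )
  if (k_hi <= k_lo) return(new_cycle_table(empty, 0L))

  bounds <- vapply((k_lo:k_hi), function(k) {
    first_up_crossing(u, -pi / 2 + 2 * pi * k)
  }, integer(1))
  ok <- !is.na(bounds)
  bounds <- bounds[ok]
  if (length(bounds) < 2L) return(new_cycle_table(empty, 0L))

  rows <- list()
  for (j in seq_len(length(bounds) - 1L)) {
    s <- bounds[j]; e <- bounds[j + 1L] - 1L
    if (s <= 1L || e >= n) next  # edge cycle touching a segment boundary
    span <- s:e
    useg <- u[c(span, e + 1L)]
    base <- -pi / 2 + 2 * pi * round((useg[1] + pi / 2) / (2 * pi))
    targets <- base + pi / 2 * (1:3)  # peak, descending zero, trough
    cnts <- vapply(targets, function(tg) count_crossings(useg, tg), numeric(2))
    controls_ok <- all(cnts["up", ] == 1) && all(cnts["down", ] == 0)
    pts <- vapply(targets, function(tg) {
      i <- first_up_crossing(useg, tg)
      if (is.na(i)) NA_integer_ else s + i - 2L  # last sample before crossing
    }, integer(1))
    rows[[length(rows) + 1L]] <- tibble(
      start = s, end = e,
      pt_asc_zero = s, pt_peak = pts[1], pt_desc_zero = pts[2],
      pt_trough = pts[3],
      mean_amplitude = mean(attr$amplitude[span]),
      controls_ok = controls_ok,
      no_phase_reversal = all(diff(u[span]) > 0)
    )
  }
  if (length(rows) == 0) return(new_cycle_table(empty, 0L))
  tbl <- dplyr::bind_rows(rows)
  thresh <- quantile(tbl$mean_amplitude, amplitude_percentile / 100, names = FALSE)
  tbl$amplitude_ok <- tbl$mean_amplitude >= thresh
  tbl$accepted <- tbl$amplitude_ok & tbl$controls_ok & tbl$no_phase_reversal
  tbl <- dplyr::mutate(tbl, cycle = dplyr::row_number(), .before = 1)
  tbl <- dplyr::relocate(tbl, "amplitude_ok", .after = "mean_amplitude")
  new_cycle_table(tbl, nrow(tbl))
}

new_cycle_table <- function(tbl, n_detected) {
  attr(tbl, "n_detected") <- n_detected
  class(tbl) <- c("cycle_table", class(tbl))
  tbl
}

#' Summarize a cycle table
#'
#' @param x A `cycle_table`.
#' @param ... Unused.
#' @return One-row tibble with detection and QC counts.
#' @method glance cycle_table
#' @export
glance.cycle_table <- function(x, ...) {
  tibble(
    n_detected = attr(x, "n_detected") %||% nrow(x),
    n_accepted = sum(x$accepted),
    n_rejected_amplitude = sum(!x$amplitude_ok),
    n_rejected_controls = sum(!x$controls_ok),
    n_rejected_reversal = sum(!x$no_phase_reversal)
  )
}
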