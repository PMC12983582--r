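#' Phase-aligned instantaneous frequency matrix
#'
#' Projects the instantaneous frequency of each accepted cycle onto a common
#' regular phase grid of `n_bins` bins spanning \eqn{[-\pi, \pi)} (peak at
#' phase 0, trough at the edges), so that peaks are compared with peaks
#' across cycles. Values are interpolated from the cycle's unwrapped phase.
#'
#' @param cycles A [detect_cycles()] table; only accepted cycles are used.
#' @param attr The [instantaneous_attributes()] the cycles were detected on.
#' @param n_bins Number of phase bins.
#' @param info Optional tibble (or one-row data frame) of provenance columns
#'   recycled to the accepted cycles (e.g. component, time point, lobe).
#' @return An object of class `ifpa_matrix`: list with `values` (cycles x
#'   bins matrix of IF in Hz), `phase` (bin centers), `info` (per-row
#'   provenance tibble including `cycle`).
#' @export
phase_align_if <- function(cycles, attr, n_bins = 48L, info = NULL) {
  stopifnot(inherits(cycles, "cycle_table"), inherits(attr, "inst_attributes"))
  check_scalar(n_bins, "n_bins", lower = 4)
  n_bins <- as.integer(n_bins)
  acc <- cycles[cycles$accepted, , drop = FALSE]
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  centers <- edges[-(n_bins + 1L)] + diff(edges) / 2

  u <- attr$phase_unwrapped
  f <- attr$if_hz
  rows <- list()
  kept <- integer(0)
  for (r in seq_len(nrow(acc))) {
    s <- acc$start[r]; e <- acc$end[r]
    if (e - s + 1L < 4L) {
      warn(sprintf("Cycle %d has fewer than 4 samples; skipped.", acc$cycle[r]))
      next
    }
    # widen by one sample each side so interpolation covers the full span
    s2 <- max(1L, s - 1L); e2 <- min(length(u), e + 1L)
    useg <- u[s2:e2]; fseg <- f[s2:e2]
    # cycle covers unwrapped phase [c0, c0 + 2*pi), c0 at the ascending zero
    c0 <- -pi / 2 + 2 * pi * round((u[s] + pi / 2) / (2 * pi))
    # map each grid center into the cycle's unwrapped interval
    targ <- centers + 2 * pi * ceiling((c0 - centers) / (2 * pi))
    ord <- order(useg)
    vals <- approx(useg[ord], fseg[ord], xout = targ, rule = 2, ties = mean)$y
    rows[[length(rows) + 1L]] <- vals
    kept <- c(kept, acc$cycle[r])
  }
  values <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, n_bins)
  info_tbl <- tibble(cycle = kept)
  if (!is.null(info)) {
    info <- as_tibble(info)
    if (nrow(info) == 1L) info <- info[rep(1L, length(kept)), , drop = FALSE]
    if (nrow(info) == length(kept)) info_tbl <- dplyr::bind_cols(info_tbl, info)
  }
  structure(list(values = values, phase = centers, info = info_tbl),
            class = "ifpa_matrix")
}

#' @export
print.ifpa_matrix <- function(x, ...) {
  cat(sprintf("<ifpa_matrix> %d cycle(s) x %d phase bins\n",
              nrow(x$values), length(x$phase)))
  invisible(x)
}

#' Bind phase-aligned IF matrices by row
#'
#' @param ... `ifpa_matrix` objects with identical phase grids.
#' @return A pooled `ifpa_matrix`.
#' @export
bind_ifpa <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "ifpa_matrix")) {
    ms <- ms[[1]]
  }
  stopifnot(all(vapply(ms, inherits, logical(1), "ifpa_matrix")))
  ph <- ms[[1]]$phase
  for (m in ms) stopifnot(isTRUE(all.equal(m$phase, ph)))
  structure(
    list(values = do.call(rbind, lapply(ms, `[[`, "values")),
         phase = ph,
         info = dplyr::bind_rows(lapply(ms, `[[`, "info"))),
    class = "ifpa_matrix"
  )
}

#' @method tidy ifpa_matrix
#' @export
tidy.ifpa_matrix <- function(x, ...) {
  long <- as_tibble(x$values, .name_repair = ~ sprintf("bin%02d", seq_along(.x)))
  long <- dplyr::bind_cols(x$info, long)
  tidyr::pivot_longer(long, dplyr::starts_with("bin"), names_to = "bin",
                      values_to = "if_value") |>
    dplyr::mutate(phase = x$phase[as.integer(sub("bin", "", .data$bin))])
}

#' Normalize phase-aligned IF to relative (dimensionless) values
#'
#' Divides every entry by the grand mean IF of its normalization group
#' (default: one global group; pass a grouping vector or the name of an
#' `info` column, e.g. component x time point, to normalize within groups),
#' yielding relative IF with group mean 1. This removes differences in mean
#' frequency between conditions while preserving within-group shape
#' variance ratios.
#'
#' @param m An `ifpa_matrix` with strictly positive values.
#' @param group `NULL` (global), a vector with one element per row, or the
#'   name(s) of `info` columns to group by.
#' @return An `ifpa_matrix` of relative IF.
#' @export
normalize_ifpa <- function(m, group = NULL) {
  stopifnot(inherits(m, "ifpa_matrix"))
  if (nrow(m$values) == 0) return(m)
  if (any(m$values <= 0)) abort("IF values must be strictly positive to normalize.")
  g <- if (is.null(group)) {
    rep(1L, nrow(m$values))
  } else if (is.character(group) && all(group %in% names(m$info))) {
    interaction(m$info[group], drop = TRUE)
  } else {
    if (length(group) != nrow(m$values)) abort("`group` length must match rows.")
    group
  }
  out <- m
  for (lev in unique(g)) {
    idx <- which(g == lev)
    out$values[idx, ] <- m$values[idx, , drop = FALSE] /
      mean(m$values[idx, , drop = FALSE])
  }
  out
}

#' Extract waveform motifs by principal component analysis
#'
#' Column-demeans the phase-aligned IF matrix and extracts principal
#' components: each retained component is a waveform motif over phase bins
#' describing one axis of cycle-shape variation, with per-cycle scores given
#' by projection. Component signs are fixed so that the largest-magnitude
#' loading is positive, and the convention is recorded. Scores are mean zero
#' by construction, and explained-variance fractions are non-increasing.
#'
#' @param m An `ifpa_matrix` (typically normalized, pooled over conditions).
#' @param n_keep Number of motifs to retain.
#' @return An object of class `motif_model`: `mean_profile`, `loadings`
#'   (bins x `n_keep`), `scores` (cycles x `n_keep`, with provenance in
#'   `info`), `var_explained` (all components), `sign_flipped` record,
#'   `phase` grid.
#' @export
fit_motifs <- function(m, n_keep = 4L) {
  stopifnot(inherits(m, "ifpa_matrix"))
  if (nrow(m$values) < 2L) abort("Need at least 2 cycles to fit motifs.")
  n_keep <- min(as.integer(n_keep), ncol(m$values))
  pc <- prcomp(m$values, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation[, seq_len(n_keep), drop = FALSE]
  scores <- pc$x[, seq_len(n_keep), drop = FALSE]
  flipped <- logical(n_keep)
  for (j in seq_len(n_keep)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
      flipped[j] <- TRUE
    }
  }
  colnames(load) <- colnames(scores) <- sprintf("PC%d", seq_len(n_keep))
  structure(
    list(mean_profile = colMeans(m$values), loadings = load, scores = scores,
         var_explained = var_all, n_keep = n_keep, sign_flipped = flipped,
         phase = m$phase, info = m$info),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %d motif(s) over %d phase bins, %d cycles\n",
              x$n_keep, length(x$phase), nrow(x$scores)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * head(x$var_explained, x$n_keep)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_motifs
#' @param x A `motif_model`.
#' @param ... Unused.
#' @method tidy motif_model
#' @export
tidy.motif_model <- function(x, ...) {
  as_tibble(x$loadings) |>
    dplyr::mutate(phase = x$phase, .before = 1) |>
    tidyr::pivot_longer(-"phase", names_to = "component", values_to = "loading")
}

#' @rdname fit_motifs
#' @method glance motif_model
#' @export
glance.motif_model <- function(x, ...) {
  tibble(
    component = sprintf("PC%d", seq_len(x$n_keep)),
    var_explained = head(x$var_explained, x$n_keep),
    cum_var_explained = cumsum(head(x$var_explained, x$n_keep))
  )
}

#' Per-cycle motif scores with provenance
#'
#' @param model A `motif_model`.
#' @return A tibble: provenance columns followed by one score column per
#'   retained motif.
#' @export
motif_scores <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  dplyr::bind_cols(model$info, as_tibble(model$scores))
}

#' Split-half reliability of motif loadings
#'
#' Randomly halves the cycle rows `n_splits` times, fits a PCA to each half,
#' matches components greedily across halves by absolute loading
#' correlation, and records the sign-aligned correlation per component.
#'
#' @param m An `ifpa_matrix` with at least 4 rows.
#' @param n_splits Number of random splits.
#' @param n_components Number of components compared.
#' @param seed Optional integer seed (same seed, identical report).
#' @return An object of class `reliability_report`: tibble `splits`
#'   (`split`, `component`, `correlation`) plus a `summary` tibble with the
#'   per-component median and IQR.
#' @export
split_half_reliability <- function(m, n_splits = 500L, n_components = 4L,
                                   seed = NULL) {
  stopifnot(inherits(m, "ifpa_matrix"))
  n <- nrow(m$values)
  if (n < 4L) abort("Need at least 4 cycles for split-half reliability.")
  if (!is.null(seed)) set.seed(seed)
  n_components <- min(as.integer(n_components), ncol(m$values))
  res <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    idx <- sample.int(n, n %/% 2L)
    l1 <- prcomp(m$values[idx, , drop = FALSE], center = TRUE)$rotation
    l2 <- prcomp(m$values[-idx, , drop = FALSE], center = TRUE)$rotation
    k <- min(n_components, ncol(l1), ncol(l2))
    cm <- abs(stats::cor(l1[, seq_len(k), drop = FALSE],
                         l2[, seq_len(k), drop = FALSE]))
    # greedy matching in component order of the first half
    avail <- seq_len(k)
    corr <- numeric(k)
    for (j in seq_len(k)) {
      best <- avail[which.max(cm[j, avail])]
      corr[j] <- cm[j, best]
      avail <- setdiff(avail, best)
    }
    res[[s]] <- tibble(split = s, component = sprintf("PC%d", seq_len(k)),
                       correlation = corr)
  }
  splits <- dplyr::bind_rows(res)
  summary <- splits |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(median = median(.data$correlation),
                     iqr = IQR(.data$correlation), .groups = "drop")
  structure(list(splits = splits, summary = summary, n_splits = n_splits),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %d splits\n", x$n_splits))
  print(x$summary)
  invisible(x)
}

#' @rdname split_half_reliability
#' @param x A `reliability_report`.
#' @param ... Unused.
#' @method tidy reliability_report
#' @export
tidy.reliability_report <- function(x, ...) x$splits

#' @rdname split_half_reliability
#' @method glance reliability_report
#' @export
glance.reliability_report <- function(x, ...) x$summary

#' Reconstruct a normalized waveform from a relative IF profile
#'
#' Inverts the IF-by-phase description: the time spent in each phase bin is
#' proportional to the reciprocal of the profile, cumulative time maps back
#' to phase, and the waveform is \eqn{\cos\phi} resampled on a uniform time
#' grid covering exactly one cycle (duration normalized to 1). A flat
#' profile reproduces a pure cosine; a profile elevated around phase 0
#' narrows the peak.
#'
#' @param profile Strictly positive relative IF values over the phase bins
#'   (bin centers assumed equispaced on \eqn{[-\pi, \pi)}).
#' @param n_samples Number of output samples.
#' @return A tibble with columns `time` (cycle fraction, `[0, 1)`), `phase`
#'   and `waveform`.
#' @export
#' @examples
#' reconstruct_waveform(rep(1, 48))
reconstruct_waveform <- function(profile, n_samples = 480L) {
  profile <- as.numeric(profile)
  if (any(!is.finite(profile)) || any(profile <= 0)) {
    abort("`profile` must be strictly positive.")
  }
  nb <- length(profile)
  dphi <- 2 * pi / nb
  edges <- seq(-pi, pi, length.out = nb + 1L)
  dt <- dphi / profile
  t_edges <- c(0, cumsum(dt))
  t_edges <- t_edges / t_edges[nb + 1L]  # normalize duration to one cycle
  ts <- seq(0, 1, length.out = n_samples + 1L)[seq_len(n_samples)]
  phi <- approx(t_edges, edges, xout = ts, rule = 2)$y
  tibble(time = ts, phase = phi, waveform = cos(phi))
}
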