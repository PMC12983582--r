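#' Alpha band and flanking bands around an individual peak frequency
#'
#' The signal band of interest is the individual alpha peak frequency plus or
#' minus `half_width`; the flanking (noise) bands are the `flank_width`-wide
#' bands abutting it on either side. For an IAF of 10 Hz with defaults this
#' gives a signal band of 8-12 Hz with flanks 6-8 and 12-14 Hz.
#'
#' @param iaf Individual alpha peak frequency (Hz).
#' @param half_width Signal-band half width (Hz).
#' @param flank_width Flanking-band width (Hz).
#' @return An object of class `ssd_bands`: list with `center`, `signal`,
#'   `flank_lo`, `flank_hi` (each a `c(lo, hi)` pair in Hz).
#' @export
#' @examples
#' define_bands(10)
define_bands <- function(iaf, half_width = 2, flank_width = 2) {
  check_scalar(iaf, "iaf", lower = .Machine$double.eps)
  check_scalar(half_width, "half_width", lower = .Machine$double.eps)
  check_scalar(flank_width, "flank_width", lower = .Machine$double.eps)
  lo <- iaf - half_width - flank_width
  if (lo <= 0) abort("Lower flank reaches 0 Hz; decrease the widths or raise `iaf`.")
  structure(
    list(center = iaf,
         signal = c(iaf - half_width, iaf + half_width),
         flank_lo = c(lo, iaf - half_width),
         flank_hi = c(iaf + half_width, iaf + half_width + flank_width)),
    class = "ssd_bands"
  )
}

#' @export
print.ssd_bands <- function(x, ...) {
  cat(sprintf("<ssd_bands> signal %g-%g Hz, flanks %g-%g / %g-%g Hz\n",
              x$signal[1], x$signal[2], x$flank_lo[1], x$flank_lo[2],
              x$flank_hi[1], x$flank_hi[2]))
  invisible(x)
}

# zero-phase Butterworth band-pass / band-stop, applied per channel (rows)
filter_channels <- function(data, fs, band, type = c("pass", "stop"), order = 2) {
  type <- match.arg(type)
  w <- band / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) abort("Filter band outside (0, Nyquist).")
  flt <- signal::butter(order, w, type = type)
  t(apply(data, 1, function(x) signal::filtfilt(flt, x)))
}

shrink_cov <- function(C, gamma) {
  (1 - gamma) * C + gamma * (sum(diag(C)) / nrow(C)) * diag(nrow(C))
}

#' Spatio-spectral decomposition (SSD)
#'
#' Finds spatial filters that maximize signal-band power relative to
#' flanking-band power by solving the generalized eigenproblem
#' \eqn{C_s w = \lambda C_n w}, where \eqn{C_s} is the covariance of the
#' signal-band-filtered data and \eqn{C_n} the covariance of the
#' flank-filtered data (band-pass over the full flank range, then band-stop
#' over the widened signal band). Filters are sorted by descending
#' eigenvalue, and spatial patterns are recovered with the Haufe identity
#' \eqn{A = C_s W (W^\top C_s W)^{-1}}.
#'
#' @param rec An [eeg_recording()] of at least 10 s.
#' @param band An [define_bands()] result.
#' @param gamma Covariance shrinkage parameter.
#' @param edge Seconds discarded at each end after filtering, to suppress
#'   filter transients, before covariance estimation.
#' @return An object of class `ssd_model`: filters `W` (channels x
#'   components), patterns `A`, eigenvalues `lambda` (descending), the band
#'   definition, channel labels, and the two covariance matrices.
#' @export
fit_ssd <- function(rec, band, gamma = 1e-6, edge = 1) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "ssd_bands"))
  if (ncol(rec$data) / rec$fs < 10) abort("Recording shorter than 10 s.")
  if (band$flank_hi[2] >= rec$fs / 2) abort("Band definition exceeds Nyquist.")

  X <- rec$data - rowMeans(rec$data)
  xs <- filter_channels(X, rec$fs, band$signal, "pass")
  xn <- filter_channels(X, rec$fs, c(band$flank_lo[1], band$flank_hi[2]), "pass")
  xn <- filter_channels(xn, rec$fs, c(band$signal[1] - 1, band$signal[2] + 1), "stop")

  cut <- round(edge * rec$fs)
  keep <- (cut + 1):(ncol(X) - cut)
  Cs <- stats::cov(t(xs[, keep, drop = FALSE]))
  Cn <- stats::cov(t(xn[, keep, drop = FALSE]))
  Cs <- shrink_cov(Cs, gamma)
  Cn <- shrink_cov(Cn, gamma)

  en <- eigen(Cn, symmetric = TRUE)
  tol <- max(en$values) * 1e-10
  pos <- en$values > tol
  if (!any(pos)) abort("Noise covariance is numerically rank deficient beyond regularization.")
  Wh <- en$vectors[, pos, drop = FALSE] %*% diag(1 / sqrt(en$values[pos]),
                                                 nrow = sum(pos))
  M <- t(Wh) %*% Cs %*% Wh
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  W <- Wh %*% em$vectors
  lambda <- em$values
  ord <- order(lambda, decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  lambda <- lambda[ord]
  A <- Cs %*% W %*% solve(t(W) %*% Cs %*% W)

  # fix component polarity: waveform shape is not invariant to signal
  # inversion (peaks and troughs swap), so make the largest-|weight| pattern
  # entry positive and flip the filter with it (Haufe identity is preserved
  # under a joint sign flip)
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) {
      A[, j] <- -A[, j]
      W[, j] <- -W[, j]
    }
  }

  structure(
    list(filters = W, patterns = A, lambda = lambda, band = band,
         labels = rec$labels, cov_signal = Cs, cov_noise = Cn),
    class = "ssd_model"
  )
}

#' @export
print.ssd_model <- function(x, ...) {
  cat(sprintf("<ssd_model> %d channels, %d components; lambda[1] = %.3f\n",
              nrow(x$filters), ncol(x$filters), x$lambda[1]))
  invisible(x)
}

#' @rdname fit_ssd
#' @param x An `ssd_model`.
#' @param ... Unused.
#' @method tidy ssd_model
#' @export
tidy.ssd_model <- function(x, ...) {
  tibble(component = seq_along(x$lambda), lambda = x$lambda)
}

#' @rdname fit_ssd
#' @method glance ssd_model
#' @export
glance.ssd_model <- function(x, ...) {
  tibble(n_channels = nrow(x$filters), n_components = ncol(x$filters),
         lambda_max = x$lambda[1],
         signal_band_lo = x$band$signal[1], signal_band_hi = x$band$signal[2])
}

#' Apply SSD spatial filters to broadband data
#'
#' Projects the (broadband) recording through the first `k` SSD filters,
#' preserving broadband content: the narrowband filtering used to estimate
#' the covariances is not applied to the output series.
#'
#' @param rec An [eeg_recording()] with the same channel order as used in
#'   [fit_ssd()].
#' @param ssd An `ssd_model`.
#' @param k Number of leading components to extract; `k = 0` returns an
#'   empty component set.
#' @return An object of class `ssd_components`: list with `series`
#'   (k x samples matrix), `fs`, and component indices.
#' @export
apply_filters <- function(rec, ssd, k = ncol(ssd$filters)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(ssd, "ssd_model"))
  if (nrow(rec$data) != nrow(ssd$filters)) {
    abort("Channel count mismatch between recording and SSD filters.")
  }
  if (!identical(rec$labels, ssd$labels)) {
    abort("Channel labels differ from those used to fit the SSD model.")
  }
  check_scalar(k, "k", lower = 0, upper = ncol(ssd$filters))
  k <- as.integer(k)
  series <- if (k == 0) {
    matrix(numeric(0), nrow = 0, ncol = ncol(rec$data))
  } else {
    t(ssd$filters[, seq_len(k), drop = FALSE]) %*% rec$data
  }
  structure(list(series = series, fs = rec$fs, components = seq_len(k)),
            class = "ssd_components")
}

#' @export
print.ssd_components <- function(x, ...) {
  cat(sprintf("<ssd_components> %d component(s) x %d samples @ %g Hz\n",
              nrow(x$series), ncol(x$series), x$fs))
  invisible(x)
}

#' Select SSD components by alpha peak presence and SNR
#'
#' Fits a multitaper spectrum and spectrum model to each component time
#' series and retains components that have an oscillatory peak in the alpha
#' band with SNR strictly exceeding `snr_threshold`. The exclusion reason is
#' recorded per dropped component.
#'
#' @param comps An `ssd_components` object.
#' @param snr_threshold SNR threshold in dB (components must exceed it).
#' @param band Alpha band in Hz.
#' @param epoch_len,fmin,fmax Passed to [multitaper_psd()].
#' @param ... Passed to [fit_spectral_model()].
#' @return A tibble with one row per component: `component`, `iaf`,
#'   `snr_db`, `retained`, `reason` (`"ok"`, `"no-peak"` or `"low-snr"`).
#' @export
select_components <- function(comps, snr_threshold = 3.87, band = c(7, 14),
                              epoch_len = 10, fmin = 2, fmax = 40, ...) {
  stopifnot(inherits(comps, "ssd_components"))
  purrr::map_dfr(seq_len(nrow(comps$series)), function(i) {
    rec_i <- eeg_recording(comps$series[i, , drop = FALSE], fs = comps$fs,
                           labels = sprintf("comp%02d", i))
    model <- fit_spectral_model(
      multitaper_psd(rec_i, epoch_len = epoch_len, fmin = fmin, fmax = fmax), ...
    )
    snr <- alpha_snr(model, band = band)
    pk <- model$peaks[model$peaks$center >= band[1] & model$peaks$center <= band[2], ]
    iaf <- if (nrow(pk)) pk$center[which.max(pk$height)] else NA_real_
    reason <- if (is.na(snr)) "no-peak" else if (snr <= snr_threshold) "low-snr" else "ok"
    tibble(component = i, iaf = iaf, snr_db = snr,
           retained = reason == "ok", reason = reason)
  })
}
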