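# ---- discrete prolate spheroidal sequences -------------------------------

# DPSS via the symmetric tridiagonal eigenproblem; for long windows the
# tapers are solved on a 512-point grid and spline-interpolated, then
# re-orthonormalized (ample accuracy for PSD estimation).
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  n <- as.integer(n)
  k <- as.integer(k)
  stopifnot(n >= 8, k >= 1, nw > 0, k <= n)
  solve_exact <- function(nn) {
    w <- nw / nn
    i <- seq_len(nn) - 1
    diag_v <- ((nn - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
    off_v <- (i[-1] * (nn - i[-1])) / 2
    A <- matrix(0, nn, nn)
    A[cbind(seq_len(nn), seq_len(nn))] <- diag_v
    A[cbind(seq_len(nn - 1), 2:nn)] <- off_v
    A[cbind(2:nn, seq_len(nn - 1))] <- off_v
    e <- eigen(A, symmetric = TRUE)
    e$vectors[, seq_len(k), drop = FALSE]
  }
  if (n <= 640L) {
    v <- solve_exact(n)
  } else {
    n0 <- 512L
    v0 <- solve_exact(n0)
    x0 <- seq(0, 1, length.out = n0)
    x1 <- seq(0, 1, length.out = n)
    v <- apply(v0, 2, function(col) splinefun(x0, col)(x1))
    v <- qr.Q(qr(v))  # re-orthonormalize, preserving the leading-order span
  }
  # sign convention: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) v[, j] <- -v[, j]
    } else if (v[2, j] - v[1, j] < 0) {
      v[, j] <- -v[, j]
    }
  }
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  # concentration in [-W, W], computed spectrally, used as weights
  nfft <- 2^ceiling(log2(4 * n))
  lam <- vapply(seq_len(k), function(j) {
    p <- Mod(fft(c(v[, j], numeric(nfft - n))))^2
    f <- seq(0, 1, length.out = nfft + 1L)[seq_len(nfft)]
    inw <- f <= nw / n | f >= 1 - nw / n
    sum(p[inw]) / sum(p)
  }, numeric(1))
  list(tapers = v, concentrations = pmin(lam, 1))
}

#' Multitaper power spectral density
#'
#' Splits the recording into fixed-length epochs, applies discrete prolate
#' (Slepian) tapers with time-half-bandwidth `nw` to each demeaned epoch, and
#' averages the eigenvalue-weighted taper spectra over epochs and over the
#' requested channels. The returned spectrum is restricted to
#' `[fmin, fmax]`.
#'
#' @param rec An [eeg_recording()].
#' @param channels Channel labels or indices to average over; default all.
#' @param epoch_len Epoch length in seconds.
#' @param fmin,fmax Frequency range of the returned spectrum (Hz); `fmax`
#'   must not exceed Nyquist.
#' @param nw Time-half-bandwidth product; `2 * nw - 1` tapers are used.
#'
#' @return An object of class `eeg_spectrum`: list with `freqs` (Hz),
#'   `power` (linear, uV^2/Hz), `n_epochs`, `fs`.
#' @export
#' @examples
#' sim <- make_recording(list(), n_channels = 2, duration = 20, fs = 250,
#'                       chi = 1, seed = 1)
#' sp <- multitaper_psd(sim$recording, epoch_len = 10)
multitaper_psd <- function(rec, channels = NULL, epoch_len = 10,
                           fmin = 2, fmax = 40, nw = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  check_scalar(epoch_len, "epoch_len", lower = .Machine$double.eps)
  if (fmax > rec$fs / 2 + 1e-9) abort("`fmax` exceeds the Nyquist frequency.")
  if (fmin >= fmax) abort("`fmin` must be below `fmax`.")
  idx <- resolve_channels(rec, channels)

  n_ep_samp <- round(epoch_len * rec$fs)
  n_total <- ncol(rec$data)
  n_epochs <- n_total %/% n_ep_samp
  if (n_epochs < 1L) abort("Recording shorter than one epoch.")

  dp <- dpss_tapers(n_ep_samp, nw = nw)
  v <- dp$tapers
  lam <- dp$concentrations
  freqs <- seq(0, rec$fs, length.out = n_ep_samp + 1L)[seq_len(n_ep_samp)]
  keep <- which(freqs >= fmin & freqs <= fmax + 1e-12)

  acc <- numeric(length(keep))
  for (ch in idx) {
    for (e in seq_len(n_epochs)) {
      seg <- rec$data[ch, ((e - 1L) * n_ep_samp + 1L):(e * n_ep_samp)]
      seg <- seg - mean(seg)
      pk <- numeric(length(keep))
      for (j in seq_len(ncol(v))) {
        X <- fft(seg * v[, j])
        pk <- pk + lam[j] * Mod(X[keep])^2
      }
      acc <- acc + pk / sum(lam)
    }
  }
  power <- 2 * acc / (n_epochs * length(idx) * rec$fs)
  structure(
    list(freqs = freqs[keep], power = power, n_epochs = n_epochs, fs = rec$fs),
    class = "eeg_spectrum"
  )
}

resolve_channels <- function(rec, channels) {
  if (is.null(channels)) return(seq_len(nrow(rec$data)))
  if (is.character(channels)) {
    idx <- match(channels, rec$labels)
    if (anyNA(idx)) {
      abort(sprintf("Unknown channel(s): %s",
                    paste(channels[is.na(idx)], collapse = ", ")))
    }
    idx
  } else {
    idx <- as.integer(channels)
    if (any(idx < 1 | idx > nrow(rec$data))) abort("Channel index out of range.")
    idx
  }
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat(sprintf("<eeg_spectrum> %d bins, %.2f-%.2f Hz, %d epochs\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$n_epochs))
  invisible(x)
}

#' @method tidy eeg_spectrum
#' @export
tidy.eeg_spectrum <- function(x, ...) tibble(freq = x$freqs, power = x$power)

#' Build a spectrum object from frequency/power vectors
#'
#' Mainly useful for constructing exact test spectra (e.g. a pure power law
#' plus Gaussian peaks) to feed [fit_spectral_model()].
#'
#' @param freqs Strictly increasing frequency grid (Hz).
#' @param power Linear power values, positive everywhere.
#' @param n_epochs Number of epochs the spectrum notionally averages.
#' @param fs Sampling rate recorded alongside.
#' @return An `eeg_spectrum`.
#' @export
as_spectrum <- function(freqs, power, n_epochs = 1L, fs = 2 * max(freqs)) {
  freqs <- as.numeric(freqs); power <- as.numeric(power)
  if (length(freqs) != length(power)) abort("`freqs` and `power` lengths differ.")
  if (any(diff(freqs) <= 0)) abort("`freqs` must be strictly increasing.")
  if (any(power <= 0)) abort("`power` must be positive.")
  structure(list(freqs = freqs, power = power, n_epochs = n_epochs, fs = fs),
            class = "eeg_spectrum")
}

# ---- aperiodic + Gaussian-peak parameterization --------------------------

gaussian_mix <- function(f, pars) {
  # pars: matrix with columns center, height, sd
  y <- numeric(length(f))
  if (is.null(pars) || nrow(pars) == 0) return(y)
  for (i in seq_len(nrow(pars))) {
    y <- y + pars[i, 2] * exp(-(f - pars[i, 1])^2 / (2 * pars[i, 3]^2))
  }
  y
}

aperiodic_values <- function(f, offset, exponent) offset - exponent * log10(f)

simple_ap_fit <- function(logf, y) {
  fit <- lm(y ~ logf)
  c(offset = unname(coef(fit)[1]), exponent = unname(-coef(fit)[2]))
}

# robust aperiodic fit: drop points whose positive residual exceeds a low
# percentile of the positive residuals (peaks bias naive fits upward)
robust_ap_fit <- function(logf, y, perc = 0.025) {
  ap <- simple_ap_fit(logf, y)
  resid <- y - (ap[1] - ap[2] * logf)
  flat <- pmax(resid, 0)
  thresh <- quantile(flat, perc, names = FALSE)
  keep <- flat <= thresh
  if (sum(keep) >= 3) ap <- simple_ap_fit(logf[keep], y[keep])
  ap
}

#' Parameterize a power spectrum into aperiodic and periodic parts
#'
#' Fits, in log10-power space, an aperiodic component
#' \eqn{b - \chi \log_{10} f} (fixed mode, no knee) plus up to `max_n_peaks`
#' Gaussian peaks. The aperiodic component is fitted robustly (points lying
#' above the initial fit beyond a low residual percentile are dropped and the
#' fit repeated), peaks are extracted iteratively from the flattened spectrum
#' (largest residual first, with height and relative-threshold checks), all
#' Gaussians are then refit jointly, and the aperiodic component is refit on
#' the peak-removed spectrum. Model quality is summarized by `r2` and mean
#' absolute error in log10-power units.
#'
#' @param spec An `eeg_spectrum`.
#' @param width_limits Numeric length-2: allowed peak bandwidths in Hz
#'   (bandwidth = 2 standard deviations of the Gaussian).
#' @param max_n_peaks Maximum number of peaks.
#' @param min_peak_height Minimum peak height in log10-power units (0.2
#'   corresponds to 2 dB).
#' @param peak_threshold Relative threshold in standard deviations of the
#'   flattened spectrum.
#'
#' @return An object of class `spectrum_model` with fields `offset`,
#'   `exponent`, `peaks` (tibble: `center`, `height`, `bandwidth`), `r2`,
#'   `error`, plus the input grid and fitted values.
#' @export
#' @examples
#' f <- seq(2, 40, by = 0.1)
#' pw <- 10^(1 - 1.5 * log10(f) + 0.5 * exp(-(f - 10)^2 / 2))
#' fit_spectral_model(as_spectrum(f, pw))
fit_spectral_model <- function(spec, width_limits = c(1, 12), max_n_peaks = 6,
                               min_peak_height = 0.2, peak_threshold = 2.0) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  if (length(spec$freqs) <= 3) abort("Spectrum too short to parameterize (<= 3 points).")
  stopifnot(length(width_limits) == 2, all(width_limits > 0), max_n_peaks >= 0)
  f <- spec$freqs
  y <- log10(spec$power)
  logf <- log10(f)
  sd_lim <- sort(width_limits) / 2

  ap <- robust_ap_fit(logf, y)
  flat <- y - aperiodic_values(f, ap[1], ap[2])
  flat_work <- flat

  guesses <- NULL
  for (i in seq_len(max_n_peaks)) {
    imax <- which.max(flat_work)
    h <- flat_work[imax]
    if (h < min_peak_height || h < peak_threshold * sd(flat_work)) break
    cf <- f[imax]
    # half-height width guess
    half <- h / 2
    li <- imax; while (li > 1 && flat_work[li] > half) li <- li - 1
    ri <- imax; while (ri < length(f) && flat_work[ri] > half) ri <- ri + 1
    fwhm <- max(f[ri] - f[li], diff(range(f)) / length(f))
    sd_g <- min(max(fwhm / 2.355, sd_lim[1]), sd_lim[2])
    guesses <- rbind(guesses, c(cf, h, sd_g))
    flat_work <- flat_work - gaussian_mix(f, matrix(c(cf, h, sd_g), 1))
  }

  peaks <- NULL
  if (!is.null(guesses)) {
    np <- nrow(guesses)
    par0 <- as.vector(t(guesses))
    lower <- rep(c(min(f), 0, sd_lim[1]), np)
    upper <- rep(c(max(f), Inf, sd_lim[2]), np)
    obj <- function(p) {
      pars <- matrix(p, ncol = 3, byrow = TRUE)
      sum((flat - gaussian_mix(f, pars))^2)
    }
    opt <- optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500))
    pars <- matrix(opt$par, ncol = 3, byrow = TRUE)
    pars <- pars[pars[, 2] >= min_peak_height, , drop = FALSE]
    if (nrow(pars) > 0) {
      pars <- pars[order(-pars[, 2]), , drop = FALSE]
      peaks <- pars
    }
  }

  peak_vals <- gaussian_mix(f, peaks)
  ap_final <- simple_ap_fit(logf, y - peak_vals)
  model_y <- aperiodic_values(f, ap_final[1], ap_final[2]) + peak_vals
  r2 <- cor(y, model_y)^2
  err <- mean(abs(y - model_y))

  peaks_tbl <- if (is.null(peaks)) {
    tibble(center = numeric(), height = numeric(), bandwidth = numeric())
  } else {
    tibble(center = peaks[, 1], height = peaks[, 2], bandwidth = 2 * peaks[, 3])
  }
  structure(
    list(offset = unname(ap_final[1]), exponent = unname(ap_final[2]),
         peaks = peaks_tbl, r2 = r2, error = err,
         freqs = f, fitted = model_y, observed = y,
         settings = list(width_limits = width_limits, max_n_peaks = max_n_peaks,
                         min_peak_height = min_peak_height,
                         peak_threshold = peak_threshold)),
    class = "spectrum_model"
  )
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("<spectrum_model> offset %.3f, exponent %.3f, %d peak(s), r2 %.4f\n",
              x$offset, x$exponent, nrow(x$peaks), x$r2))
  if (nrow(x$peaks) > 0) print(x$peaks)
  invisible(x)
}

#' @rdname fit_spectral_model
#' @param x A `spectrum_model`.
#' @param ... Unused.
#' @method tidy spectrum_model
#' @export
tidy.spectrum_model <- function(x, ...) x$peaks

#' @rdname fit_spectral_model
#' @method glance spectrum_model
#' @export
glance.spectrum_model <- function(x, ...) {
  tibble(offset = x$offset, exponent = x$exponent, n_peaks = nrow(x$peaks),
         r2 = x$r2, error = x$error)
}

#' Individual alpha peak frequency
#'
#' For each fitted model, selects the largest peak inside the alpha band and
#' summarizes across models (e.g. pre/post time points): the individual alpha
#' frequency (IAF) is the mean of the selected peak centers. Absence of any
#' in-band peak is a value (`present = FALSE`), not an error. The IAF is
#' invariant to overall power scaling of the spectrum, since scaling shifts
#' only the aperiodic offset.
#'
#' @param models A `spectrum_model` or list of them.
#' @param band Alpha search band in Hz.
#' @return A one-row tibble: `iaf`, `alpha_height` (log10-power units),
#'   `alpha_power_db`, `alpha_snr_db`, `present`.
#' @export
individual_alpha_frequency <- function(models, band = c(7, 14)) {
  if (inherits(models, "spectrum_model")) models <- list(models)
  if (length(models) < 1) abort("Need at least one spectrum model.")
  picks <- purrr::map_dfr(models, function(m) {
    pk <- m$peaks[m$peaks$center >= band[1] & m$peaks$center <= band[2], ]
    if (nrow(pk) == 0) return(tibble(center = NA_real_, height = NA_real_))
    pk <- pk[which.max(pk$height), ]
    tibble(center = pk$center, height = pk$height)
  })
  present <- any(!is.na(picks$center))
  if (!present) {
    return(tibble(iaf = NA_real_, alpha_height = NA_real_,
                  alpha_power_db = NA_real_, alpha_snr_db = NA_real_,
                  present = FALSE))
  }
  h <- mean(picks$height, na.rm = TRUE)
  tibble(
    iaf = mean(picks$center, na.rm = TRUE),
    alpha_height = h,
    alpha_power_db = 10 * h,
    alpha_snr_db = 10 * h,
    present = TRUE
  )
}

#' Alpha SNR of a fitted spectrum model
#'
#' The elevation of the largest alpha-band peak above the aperiodic fit,
#' expressed in dB: `10 *` height in log10-power units (a height of 0.387
#' log10 units is 3.87 dB).
#'
#' @param model A `spectrum_model`.
#' @param band Alpha band in Hz.
#' @return SNR in dB, or `NA` if no in-band peak is present.
#' @export
alpha_snr <- function(model, band = c(7, 14)) {
  stopifnot(inherits(model, "spectrum_model"))
  pk <- model$peaks[model$peaks$center >= band[1] & model$peaks$center <= band[2], ]
  if (nrow(pk) == 0) return(NA_real_)
  10 * max(pk$height)
}
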