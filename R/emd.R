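# ---- envelope and sifting helpers ----------------------------------------

# spline envelope through the given extrema, with mirrored edge extrema to
# stabilize the spline near the boundaries
spline_envelope <- function(x, idx, n) {
  if (length(idx) < 2L) return(rep(mean(x[idx]), n))
  xi <- idx; yi <- x[idx]
  # mirror up to two extrema around each boundary
  k <- min(2L, length(idx))
  left_x <- 2 * 1 - xi[seq_len(k)]
  left_y <- yi[seq_len(k)]
  right_x <- 2 * n - rev(tail(xi, k))
  right_y <- rev(tail(yi, k))
  ord <- order(c(left_x, xi, right_x))
  xs <- c(left_x, xi, right_x)[ord]
  ys <- c(left_y, yi, right_y)[ord]
  dup <- duplicated(xs)
  splinefun(xs[!dup], ys[!dup], method = "fmm")(seq_len(n))
}

# one sift: extract the fastest locally-symmetric component of x.
# Rilling-style stopping: iterate while the mean-envelope-to-amplitude ratio
# is large, with an iteration cap for bounded runtime.
sift_imf <- function(x, max_iter = 15L, theta1 = 0.05, theta2 = 0.5, alpha = 0.05) {
  h <- x
  n <- length(x)
  for (it in seq_len(max_iter)) {
    mx <- local_maxima(h)
    mn <- local_minima(h)
    if (length(mx) < 2L || length(mn) < 2L) break
    eu <- spline_envelope(h, mx, n)
    el <- spline_envelope(h, mn, n)
    m <- (eu + el) / 2
    a <- pmax(abs(eu - el) / 2, .Machine$double.eps)
    sx <- abs(m) / a
    if (mean(sx > theta1) < alpha && all(sx < theta2)) {
      h <- h - m
      break
    }
    h <- h - m
  }
  h
}

#' Masked empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs), fast to slow,
#' using the masked sift: at each level a mask sinusoid of known frequency is
#' added to the residual before sifting, preventing mode mixing, and the
#' extracted component is averaged over several mask phases. The default mask
#' frequencies (120, 64, 32, 11, 7, 2 Hz) place the alpha rhythm in the mode
#' extracted at the 11 Hz mask. Mask frequencies at or above Nyquist are
#' skipped with a warning. The decomposition is complete: modes plus residual
#' reconstruct the input to numerical precision.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param mask_freqs Mask frequencies in Hz, fast to slow.
#' @param mask_amp Mask amplitude as a multiple of the current residual's
#'   standard deviation.
#' @param n_phases Number of equispaced mask phases averaged per level.
#' @param max_imfs Maximum number of modes generated.
#' @return An object of class `imf_set`: list with `modes` (samples x modes
#'   matrix, fast to slow), `residual`, `mask_freqs` actually used, `fs`.
#' @export
#' @examples
#' t <- seq(0, 10, by = 1 / 250)
#' imfs <- masked_sift(sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 2.5 * t), fs = 250)
masked_sift <- function(x, fs, mask_freqs = c(120, 64, 32, 11, 7, 2),
                        mask_amp = 1, n_phases = 4L, max_imfs = 6L) {
  x <- as.numeric(x)
  n <- length(x)
  check_scalar(fs, "fs", lower = .Machine$double.eps)
  usable <- mask_freqs[mask_freqs < fs / 2]
  if (length(usable) < length(mask_freqs)) {
    warn(sprintf("Skipping mask frequencies at/above Nyquist: %s Hz",
                 paste(setdiff(mask_freqs, usable), collapse = ", ")))
  }
  usable <- head(usable, max_imfs)
  if (length(usable) > 0 && n < 4 * fs / min(usable)) {
    abort("Signal too short for the slowest mask frequency.")
  }
  t <- (seq_len(n) - 1L) / fs
  residual <- x
  modes <- matrix(0, nrow = n, ncol = 0)
  used <- numeric(0)
  for (fm in usable) {
    amp <- mask_amp * sd(residual)
    if (!is.finite(amp) || amp == 0) break
    acc <- numeric(n)
    for (p in seq_len(n_phases) - 1L) {
      mask <- amp * cos(2 * pi * fm * t + p * 2 * pi / n_phases)
      acc <- acc + (sift_imf(residual + mask) - mask)
    }
    mode <- acc / n_phases
    modes <- cbind(modes, mode)
    used <- c(used, fm)
    residual <- residual - mode
  }
  colnames(modes) <- if (length(used)) sprintf("imf_%gHz", used) else NULL
  structure(list(modes = modes, residual = residual, mask_freqs = used, fs = fs),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d mode(s) x %d samples; masks: %s Hz\n",
              ncol(x$modes), nrow(x$modes),
              paste(x$mask_freqs, collapse = ", ")))
  invisible(x)
}

#' Extract the alpha mode from an IMF set
#'
#' Picks the mode with the largest share of its power inside the alpha band
#' (by periodogram integration).
#'
#' @param imfs An `imf_set`.
#' @param band Alpha band in Hz.
#' @return List with `mode` (numeric vector) and `index`.
#' @export
alpha_mode <- function(imfs, band = c(7, 14)) {
  stopifnot(inherits(imfs, "imf_set"))
  if (ncol(imfs$modes) == 0) abort("IMF set contains no modes.")
  n <- nrow(imfs$modes)
  f <- seq(0, imfs$fs, length.out = n + 1L)[seq_len(n)]
  half <- f <= imfs$fs / 2
  score <- vapply(seq_len(ncol(imfs$modes)), function(j) {
    p <- Mod(fft(imfs$modes[, j]))^2
    inb <- half & f >= band[1] & f <= band[2]
    sum(p[inb])
  }, numeric(1))
  j <- which.max(score)
  list(mode = imfs$modes[, j], index = j)
}

# analytic signal via FFT
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase, amplitude and frequency of a mode
#'
#' Uses the normalized Hilbert transform: the mode is amplitude-normalized
#' by iteratively dividing by a spline envelope through the maxima of its
#' absolute value (at most `max_norm_iter` iterations, until the normalized
#' signal's magnitude is within `1 + 1e-3`), the phase is taken from the
#' analytic signal of the normalized mode, and the instantaneous frequency
#' is the first time-derivative of the unwrapped phase, lightly smoothed
#' with a short Savitzky-Golay window. The instantaneous amplitude is the
#' accumulated envelope. Edge samples, where the analytic signal is
#' unreliable, are flagged.
#'
#' @param imf Numeric mode vector (locally symmetric about zero).
#' @param fs Sampling rate in Hz.
#' @param max_norm_iter Maximum envelope-normalization iterations.
#' @param smooth Savitzky-Golay window length in samples (odd; 0 disables).
#' @param n_edge Number of samples flagged as unreliable at each end.
#' @return An object of class `inst_attributes`: a tibble with columns
#'   `sample`, `phase` (wrapped to `[-pi, pi)`), `phase_unwrapped`,
#'   `amplitude`, `if_hz`, `edge`; the sampling rate is kept as an
#'   attribute.
#' @export
instantaneous_attributes <- function(imf, fs, max_norm_iter = 3L, smooth = 5L,
                                     n_edge = 2L) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 8L) abort("Mode too short for instantaneous attributes.")
  if (all(x == 0)) abort("Degenerate mode: all zeros.")
  env_total <- rep(1, n)
  z <- x
  for (it in seq_len(max_norm_iter)) {
    idx <- sort(unique(c(1L, local_maxima(abs(z)), n)))
    env <- spline_envelope(abs(z), idx, n)
    env <- pmax(env, max(abs(z)) * 1e-8)
    z <- z / env
    env_total <- env_total * env
    if (max(abs(z)) <= 1 + 1e-3) break
  }
  z <- pmin(pmax(z, -1), 1)
  analytic <- hilbert_analytic(z)
  phase <- Arg(analytic)
  pu <- unwrap_phase(phase)
  if_hz <- grad1(pu) * fs / (2 * pi)
  if (smooth >= 3 && n > smooth) {
    if_hz <- signal::sgolayfilt(if_hz, p = 2, n = as.integer(smooth))
  }
  edge <- rep(FALSE, n)
  ne <- min(n_edge, n)
  edge[seq_len(ne)] <- TRUE
  edge[(n - ne + 1L):n] <- TRUE
  out <- tibble(
    sample = seq_len(n), phase = phase, phase_unwrapped = pu,
    amplitude = env_total, if_hz = if_hz, edge = edge
  )
  attr(out, "fs") <- fs
  class(out) <- c("inst_attributes", class(out))
  out
}
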