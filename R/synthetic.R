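#' Shape parameters of a non-sinusoidal oscillation
#'
#' Cycle shape is injected through the phase velocity
#' \deqn{d\phi/dt = 2\pi f_0 (1 + a_{pt} \cos\phi + a_{rd} \sin\phi),}
#' with the signal defined as \eqn{\cos\phi}. The cosine term modulates speed
#' at the extrema (peak at \eqn{\phi = 0}, trough at \eqn{\phi = \pm\pi}) and
#' so controls peak-trough width asymmetry; the sine term modulates speed on
#' the edges and so controls rise-decay (edge-speed) asymmetry. Because shape
#' lives directly in instantaneous-frequency-by-phase space, the injected
#' profile is the ground truth that the downstream phase-aligned IF analysis
#' should recover.
#'
#' @param f0 Base cycle frequency in Hz.
#' @param a_pt Peak-trough width asymmetry coefficient (dimensionless).
#' @param a_rd Rise-decay speed asymmetry coefficient (dimensionless).
#' @param jitter_sd Cycle-to-cycle standard deviation applied independently to
#'   both coefficients.
#' @param tail_fraction Fraction of cycles drawn from an inflated-jitter
#'   mixture component (see [apply_intervention()]).
#' @param tail_k Jitter multiplier for the inflated mixture component.
#'
#' @return An object of class `shape_params`.
#' @export
#' @examples
#' shape_params(f0 = 10, a_pt = 0.2)
shape_params <- function(f0 = 10, a_pt = 0, a_rd = 0, jitter_sd = 0,
                         tail_fraction = 0, tail_k = 1) {
  check_scalar(f0, "f0", lower = 1e-6)
  check_scalar(a_pt, "a_pt")
  check_scalar(a_rd, "a_rd")
  check_scalar(jitter_sd, "jitter_sd", lower = 0)
  check_scalar(tail_fraction, "tail_fraction", lower = 0, upper = 1)
  check_scalar(tail_k, "tail_k", lower = 1)
  if (abs(a_pt) + abs(a_rd) >= 1) {
    abort("|a_pt| + |a_rd| must be < 1 so the phase velocity stays positive.")
  }
  structure(
    list(f0 = f0, a_pt = a_pt, a_rd = a_rd, jitter_sd = jitter_sd,
         tail_fraction = tail_fraction, tail_k = tail_k),
    class = "shape_params"
  )
}

#' @export
print.shape_params <- function(x, ...) {
  cat(sprintf(
    "<shape_params> f0 = %g Hz, a_pt = %g, a_rd = %g, jitter_sd = %g",
    x$f0, x$a_pt, x$a_rd, x$jitter_sd
  ))
  if (x$tail_fraction > 0) {
    cat(sprintf(", tails: %g%% at %gx jitter", 100 * x$tail_fraction, x$tail_k))
  }
  cat("\n")
  invisible(x)
}

# draw per-cycle (a_pt, a_rd) pairs; invalid draws (velocity could go
# non-positive) are redrawn a bounded number of times
draw_cycle_coefs <- function(shape, n_cycles) {
  a <- rep(shape$a_pt, n_cycles)
  b <- rep(shape$a_rd, n_cycles)
  inflated <- rep(FALSE, n_cycles)
  if (shape$jitter_sd > 0 || shape$tail_fraction > 0) {
    inflated <- runif(n_cycles) < shape$tail_fraction
    sds <- shape$jitter_sd * ifelse(inflated, shape$tail_k, 1)
    a <- shape$a_pt + rnorm(n_cycles, sd = sds)
    b <- shape$a_rd + rnorm(n_cycles, sd = sds)
    bad <- which(abs(a) + abs(b) >= 0.98)
    tries <- 0L
    while (length(bad) > 0 && tries < 100L) {
      a[bad] <- shape$a_pt + rnorm(length(bad), sd = sds[bad])
      b[bad] <- shape$a_rd + rnorm(length(bad), sd = sds[bad])
      bad <- bad[abs(a[bad]) + abs(b[bad]) >= 0.98]
      tries <- tries + 1L
    }
    if (length(bad) > 0) {
      a[bad] <- shape$a_pt
      b[bad] <- shape$a_rd
    }
  }
  list(a_pt = a, a_rd = b, inflated = inflated)
}

#' Generate a train of non-sinusoidal cycles with known shape
#'
#' Integrates the phase-velocity law of [shape_params()] cycle by cycle and
#' samples \eqn{\cos\phi} on a uniform time grid. Each cycle starts at the
#' ascending zero-crossing of the signal (\eqn{\phi = -\pi/2}), and per-cycle
#' realized coefficients are recorded as ground truth. With zero asymmetry and
#' zero jitter the output is an exact sampled cosine.
#'
#' @param shape A [shape_params()] object.
#' @param n_cycles Number of cycles to generate (>= 1).
#' @param fs Sampling rate in Hz; must exceed `4 * f0`.
#' @param seed Optional integer seed for the per-cycle jitter draws.
#' @param n_sub Phase sub-grid resolution per cycle used for the time
#'   integration (quadrature of `dt = dphi / velocity`).
#'
#' @return A list with elements
#'   \describe{
#'     \item{signal}{numeric vector, the sampled waveform (unit amplitude);}
#'     \item{phase}{unwrapped phase at each sample (starts at \eqn{-\pi/2});}
#'     \item{truth}{tibble with one row per cycle: realized `a_pt`, `a_rd`,
#'       `duration` (s), `start`/`end` sample indices, `inflated` flag;}
#'     \item{fs, shape}{inputs echoed back.}
#'   }
#' @export
#' @examples
#' tr <- make_cycle_train(shape_params(10, a_pt = 0.3), n_cycles = 20, fs = 250, seed = 1)
#' tr$truth
make_cycle_train <- function(shape, n_cycles, fs, seed = NULL, n_sub = 512L) {
  stopifnot(inherits(shape, "shape_params"))
  check_scalar(n_cycles, "n_cycles", lower = 1)
  check_scalar(fs, "fs", lower = 4 * shape$f0)
  if (shape$f0 >= fs / 2) abort("`f0` must be below the Nyquist frequency.")
  if (!is.null(seed)) set.seed(seed)
  n_cycles <- as.integer(n_cycles)

  coefs <- draw_cycle_coefs(shape, n_cycles)
  phi0 <- -pi / 2

  # fine phase grid across all cycles: n_sub intervals per cycle
  dphi <- 2 * pi / n_sub
  rel <- seq(0, 2 * pi, length.out = n_sub + 1L)[-(n_sub + 1L)]
  phi_fine <- phi0 + rep((seq_len(n_cycles) - 1L) * 2 * pi, each = n_sub) + rel
  a <- rep(coefs$a_pt, each = n_sub)
  b <- rep(coefs$a_rd, each = n_sub)
  vel <- 2 * pi * shape$f0 * (1 + a * cos(phi_fine) + b * sin(phi_fine))
  if (any(vel <= 0)) abort("Phase velocity non-positive; shape coefficients too large.")
  # closing grid point to complete the last cycle
  phi_all <- c(phi_fine, phi0 + n_cycles * 2 * pi)
  inv_v <- c(1 / vel, 1 / (2 * pi * shape$f0 *
    (1 + coefs$a_pt[n_cycles] * cos(phi0) + coefs$a_rd[n_cycles] * sin(phi0))))
  # trapezoidal cumulative time over the fine grid
  t_fine <- c(0, cumsum((inv_v[-1] + inv_v[-length(inv_v)]) / 2 * dphi))

  total_t <- t_fine[length(t_fine)]
  n_samp <- max(1L, round(total_t * fs))
  t_samp <- (seq_len(n_samp) - 1L) / fs
  phase <- approx(t_fine, phi_all, xout = t_samp, rule = 2)$y
  signal <- cos(phase)

  cycle_t0 <- t_fine[seq(1L, length(t_fine) - 1L, by = n_sub)]
  cycle_t1 <- t_fine[seq(n_sub + 1L, length(t_fine), by = n_sub)]
  start_idx <- pmin(n_samp, floor(cycle_t0 * fs) + 1L)
  end_idx <- pmin(n_samp, ceiling(cycle_t1 * fs))

  truth <- tibble(
    cycle = seq_len(n_cycles),
    a_pt = coefs$a_pt,
    a_rd = coefs$a_rd,
    duration = cycle_t1 - cycle_t0,
    start = as.integer(start_idx),
    end = as.integer(end_idx),
    inflated = coefs$inflated
  )
  list(signal = signal, phase = phase, truth = truth, fs = fs, shape = shape)
}

#' Specify one simulated alpha source
#'
#' @param shape A [shape_params()] object.
#' @param amplitude Root-mean-square source amplitude in microvolts.
#' @param envelope List with elements `freq` (slow amplitude-modulation
#'   frequency, Hz) and `depth` (modulation depth in `[0, 1]`). The modulation
#'   phase is drawn uniformly at random per realization.
#' @param pattern Numeric channel-weight vector mapping the source to the
#'   sensors; recycled or padded checks are not applied, its length must match
#'   the simulated channel count.
#'
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(shape, amplitude = 10, envelope = list(freq = 0.2, depth = 0.5),
                        pattern = NULL) {
  stopifnot(inherits(shape, "shape_params"))
  check_scalar(amplitude, "amplitude", lower = .Machine$double.eps)
  check_scalar(envelope$freq, "envelope$freq", lower = 0)
  check_scalar(envelope$depth, "envelope$depth", lower = 0, upper = 1)
  if (!is.null(pattern)) {
    pattern <- as.numeric(pattern)
    if (all(pattern == 0)) abort("`pattern` must have at least one nonzero entry.")
  }
  structure(
    list(shape = shape, amplitude = amplitude, envelope = envelope, pattern = pattern),
    class = "source_spec"
  )
}

# spectrally shaped 1/f^chi noise, one channel, unit RMS
pink_noise <- function(n, fs, chi, white = NULL) {
  if (is.null(white)) white <- rnorm(n)
  if (chi == 0) return(white / rms(white))
  spec <- fft(white)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]    # mirror to physical frequencies
  scale <- c(0, f[-1]^(-chi / 2))        # kill DC
  x <- Re(fft(spec * scale, inverse = TRUE)) / n
  x / rms(x)
}

#' Simulate a multichannel recording with known alpha sources
#'
#' Mixes non-sinusoidal alpha source trains (from [make_cycle_train()])
#' linearly into sensor channels and adds \eqn{1/f^\chi} background noise,
#' generated by frequency-domain shaping of white Gaussian noise with
#' independent realizations per channel plus an optional spatially correlated
#' component. The same `seed` yields a bit-identical recording and ground
#' truth.
#'
#' @param sources List of [source_spec()] objects (may be empty for a pure
#'   noise recording).
#' @param n_channels Number of sensor channels (>= number of sources).
#' @param duration Recording duration in seconds (>= 10).
#' @param fs Sampling rate in Hz.
#' @param chi Aperiodic exponent of the background noise (power ~ 1/f^chi).
#' @param noise_amp Per-channel RMS of the background noise, in microvolts.
#' @param spatial_corr Weight in `[0, 1]` of a shared (spatially correlated)
#'   noise realization mixed into every channel.
#' @param seed Optional integer seed.
#'
#' @return A list with elements `recording` (an [eeg_recording()]) and
#'   `truth` (class `sim_truth`): per-cycle ground-truth tibble (`source`,
#'   `cycle`, `start`, `end`, realized `a_pt`/`a_rd`, `amplitude`), the
#'   sources x channels `mixing` matrix, `chi` and the `seed`.
#' @export
#' @examples
#' sim <- make_recording(
#'   list(source_spec(shape_params(10, a_pt = 0.1), pattern = c(1, 0.5, 0, 0))),
#'   n_channels = 4, duration = 12, fs = 250, seed = 1
#' )
#' sim$recording
make_recording <- function(sources, n_channels, duration, fs, chi = 1.5,
                           noise_amp = 1, spatial_corr = 0, seed = NULL) {
  check_scalar(n_channels, "n_channels", lower = 1)
  check_scalar(duration, "duration", lower = 10)
  check_scalar(fs, "fs", lower = 1)
  check_scalar(chi, "chi", lower = 0)
  check_scalar(noise_amp, "noise_amp", lower = 0)
  check_scalar(spatial_corr, "spatial_corr", lower = 0, upper = 1)
  if (length(sources) > n_channels) abort("Need `n_channels` >= number of sources.")
  for (s in sources) {
    stopifnot(inherits(s, "source_spec"))
    if (s$shape$f0 >= fs / 2) abort("Source `f0` violates the Nyquist limit.")
  }
  if (!is.null(seed)) set.seed(seed)
  n_channels <- as.integer(n_channels)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs

  mixing <- matrix(0, nrow = length(sources), ncol = n_channels)
  data <- matrix(0, nrow = n_channels, ncol = n)
  truth_rows <- list()

  for (i in seq_along(sources)) {
    src <- sources[[i]]
    pattern <- src$pattern
    if (is.null(pattern)) {
      pattern <- rep(0, n_channels)
      pattern[i] <- 1
    }
    if (length(pattern) != n_channels) {
      abort(sprintf("Source %d pattern length != n_channels.", i))
    }
    mixing[i, ] <- pattern

    n_cycles <- ceiling(duration * src$shape$f0) + 2L
    train <- make_cycle_train(src$shape, n_cycles = n_cycles, fs = fs)
    sig <- train$signal
    if (length(sig) < n) sig <- c(sig, numeric(n - length(sig)))
    sig <- sig[seq_len(n)]

    env_phase <- runif(1, 0, 2 * pi)
    env <- 1 + src$envelope$depth * sin(2 * pi * src$envelope$freq * t + env_phase)
    sig <- sig * env
    scale <- src$amplitude / rms(sig)
    sig <- sig * scale

    data <- data + outer(pattern, sig)

    tr <- train$truth
    tr <- tr[tr$end <= n, , drop = FALSE]
    amp <- vapply(seq_len(nrow(tr)),
                  function(k) mean(env[tr$start[k]:tr$end[k]]) * scale,
                  numeric(1))
    truth_rows[[i]] <- tibble(
      source = i, cycle = tr$cycle, start = tr$start, end = tr$end,
      a_pt = tr$a_pt, a_rd = tr$a_rd, amplitude = amp, inflated = tr$inflated
    )
  }

  if (noise_amp > 0) {
    shared <- if (spatial_corr > 0) pink_noise(n, fs, chi) else numeric(n)
    for (ch in seq_len(n_channels)) {
      indep <- pink_noise(n, fs, chi)
      nz <- sqrt(1 - spatial_corr^2) * indep + spatial_corr * shared
      data[ch, ] <- data[ch, ] + noise_amp * nz / rms(nz)
    }
  }

  truth <- structure(
    list(
      cycles = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
        tibble(source = integer(), cycle = integer(), start = integer(),
               end = integer(), a_pt = numeric(), a_rd = numeric(),
               amplitude = numeric(), inflated = logical()),
      mixing = mixing, chi = chi, seed = seed
    ),
    class = "sim_truth"
  )
  list(recording = eeg_recording(data, fs = fs), truth = truth)
}

#' Simulation specification and intervention transforms
#'
#' `sim_spec()` bundles the sources and background parameters of a simulated
#' study condition. `apply_intervention()` returns a modified copy emulating a
#' pharmacological effect: alpha-power scaling, aperiodic flattening
#' (`chi_delta`), additive shifts of the mean shape coefficients, and tail
#' inflation (a stated fraction of cycles drawn with `k`-fold jitter SD,
#' producing heavier-tailed shape-score distributions).
#'
#' @param sources List of [source_spec()] objects.
#' @param n_channels,duration,fs,chi,noise_amp,spatial_corr Passed to
#'   [make_recording()].
#' @return `sim_spec()` returns an object of class `sim_spec`;
#'   `apply_intervention()` a modified `sim_spec`.
#' @export
sim_spec <- function(sources, n_channels = 8, duration = 120, fs = 250,
                     chi = 1.5, noise_amp = 1, spatial_corr = 0) {
  structure(
    list(sources = sources, n_channels = n_channels, duration = duration,
         fs = fs, chi = chi, noise_amp = noise_amp, spatial_corr = spatial_corr),
    class = "sim_spec"
  )
}

#' @param spec A `sim_spec`.
#' @param power_scale Multiplier applied to alpha-band power (amplitudes are
#'   scaled by its square root).
#' @param chi_delta Added to the aperiodic exponent (negative = flattening).
#' @param a_pt_shift,a_rd_shift Added to the mean shape coefficients of every
#'   source.
#' @param tail_inflation Either `NULL` or a list/vector `(fraction, k)`.
#' @rdname sim_spec
#' @export
#' @examples
#' base <- sim_spec(list(source_spec(shape_params(10, jitter_sd = 0.05),
#'                                   pattern = c(1, 0, 0, 0))),
#'                  n_channels = 4)
#' post <- apply_intervention(base, power_scale = 0.5, a_pt_shift = 0.1,
#'                            tail_inflation = c(0.2, 3))
apply_intervention <- function(spec, power_scale = 1, chi_delta = 0,
                               a_pt_shift = 0, a_rd_shift = 0,
                               tail_inflation = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  check_scalar(power_scale, "power_scale", lower = 0)
  out <- spec
  out$chi <- spec$chi + chi_delta
  if (out$chi < 0) abort("`chi_delta` drives the aperiodic exponent negative.")
  out$sources <- lapply(spec$sources, function(src) {
    sh <- src$shape
    new_shape <- shape_params(
      f0 = sh$f0,
      a_pt = sh$a_pt + a_pt_shift,
      a_rd = sh$a_rd + a_rd_shift,
      jitter_sd = sh$jitter_sd,
      tail_fraction = if (is.null(tail_inflation)) sh$tail_fraction else
        as.numeric(tail_inflation[[1]]),
      tail_k = if (is.null(tail_inflation)) sh$tail_k else
        as.numeric(tail_inflation[[2]])
    )
    src$shape <- new_shape
    src$amplitude <- src$amplitude * sqrt(power_scale)
    src
  })
  out
}

#' Realize a simulation specification as a recording
#'
#' @param spec A [sim_spec()].
#' @param seed Optional integer seed.
#' @return As [make_recording()]: a list with `recording` and `truth`.
#' @export
simulate_recording <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  make_recording(spec$sources, n_channels = spec$n_channels,
                 duration = spec$duration, fs = spec$fs, chi = spec$chi,
                 noise_amp = spec$noise_amp, spatial_corr = spec$spatial_corr,
                 seed = seed)
}

#' Export simulation ground truth
#'
#' Writes the per-cycle ground-truth table as CSV and the mixing matrix,
#' aperiodic exponent and seed as JSON.
#'
#' @param truth A `sim_truth` object from [make_recording()].
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(truth, csv_path, json_path = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  json_path <- json_path %||% paste0(csv_path, ".json")
  utils::write.csv(truth$cycles, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(mixing = truth$mixing, chi = truth$chi, seed = truth$seed),
    json_path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(csv_path)
}
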