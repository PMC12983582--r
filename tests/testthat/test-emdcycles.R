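test_that("masked sift isolates a pure sinusoid in the alpha-mask mode", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  x <- cos(2 * pi * 10 * t)
  imfs <- masked_sift(x, fs)
  am <- alpha_mode(imfs)
  expect_gt(cor(am$mode, x), 0.99)
  other_var <- vapply(seq_len(ncol(imfs$modes)), function(j) var(imfs$modes[, j]),
                      numeric(1))
  expect_true(all(other_var[-am$index] < 0.05 * other_var[am$index]))
})

test_that("masked sift separates a known 10 + 2.5 Hz mixture", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  fast <- cos(2 * pi * 10 * t)
  slow <- 0.8 * cos(2 * pi * 2.5 * t + 1)
  imfs <- masked_sift(fast + slow, fs)
  cors_fast <- apply(imfs$modes, 2, cor, y = fast)
  cors_slow <- apply(imfs$modes, 2, cor, y = slow)
  expect_gt(max(abs(cors_fast)), 0.95)
  expect_gt(max(abs(cors_slow)), 0.95)
})

test_that("the decomposition is complete on arbitrary signals", {
  set.seed(41)
  fs <- 250
  x <- rnorm(fs * 10) + cos(2 * pi * 10 * (0:(fs * 10 - 1)) / fs)
  imfs <- masked_sift(x, fs)
  recon <- rowSums(imfs$modes) + imfs$residual
  expect_lt(max(abs(recon - x)) / sqrt(mean(x^2)), 1e-6)
})

test_that("masks above Nyquist are skipped with a warning", {
  fs <- 100
  x <- cos(2 * pi * 10 * (0:999) / fs)
  expect_warning(imfs <- masked_sift(x, fs), "Nyquist")
  expect_true(all(imfs$mask_freqs < fs / 2))
})

test_that("instantaneous attributes of a pure cosine are exact", {
  fs <- 250
  t <- (0:(fs * 10 - 1)) / fs
  at <- instantaneous_attributes(2.5 * cos(2 * pi * 10 * t), fs)
  interior <- 26:(nrow(at) - 25)
  expect_lt(max(abs(at$if_hz[interior] - 10)), 0.1)
  expect_lt(max(abs(at$amplitude[interior] - 2.5)) / 2.5, 0.02)
  expect_error(instantaneous_attributes(numeric(100), fs), "zero")
})

test_that("instantaneous frequency tracks a linear chirp", {
  fs <- 250
  t <- (0:(fs * 10 - 1)) / fs
  # 8 -> 12 Hz over 10 s: phase = 2*pi*(8 t + 0.2 t^2), IF = 8 + 0.4 t
  x <- cos(2 * pi * (8 * t + 0.2 * t^2))
  at <- instantaneous_attributes(x, fs)
  interior <- (fs %/% 2):(nrow(at) - fs %/% 2)
  expect_lt(max(abs(at$if_hz[interior] - (8 + 0.4 * t[interior]))), 0.2)
})

test_that("peak-trough asymmetry appears as higher IF at peaks than troughs", {
  tr <- make_cycle_train(shape_params(10, a_pt = 0.3), n_cycles = 150, fs = 250)
  at <- instantaneous_attributes(tr$signal, 250)
  cyc <- detect_cycles(at, amplitude_percentile = 0)
  faster <- at$if_hz[cyc$pt_peak] > at$if_hz[cyc$pt_trough]
  expect_gte(mean(faster), 0.95)
})

test_that("a pure sinusoid yields n-1 to n complete cycles, all passing QC at percentile 0", {
  fs <- 250
  n_per <- 40
  t <- (0:(fs * n_per / 10 - 1)) / fs
  at <- instantaneous_attributes(cos(2 * pi * 10 * t), fs)
  cyc <- detect_cycles(at, amplitude_percentile = 0)
  expect_gte(nrow(cyc), n_per - 2)
  expect_lte(nrow(cyc), n_per)
  expect_true(all(cyc$accepted))
  # control points strictly ordered within each cycle
  expect_true(all(cyc$pt_asc_zero < cyc$pt_peak &
                    cyc$pt_peak < cyc$pt_desc_zero &
                    cyc$pt_desc_zero < cyc$pt_trough))
  # boundaries from phase agree with waveform ascending zero-crossings
  x <- cos(2 * pi * 10 * t)
  wf_cross <- which(x[-1] >= 0 & x[-length(x)] < 0)
  for (s in cyc$start) expect_lte(min(abs(wf_cross - s)), 2)
})

test_that("amplitude QC matches a direct percentile oracle on the known envelope", {
  fs <- 250
  t <- (0:(fs * 60 - 1)) / fs
  env <- 1 + 0.5 * sin(2 * pi * 0.1 * t)
  x <- env * cos(2 * pi * 10 * t)
  at <- instantaneous_attributes(x, fs)
  cyc <- detect_cycles(at, amplitude_percentile = 75)
  # oracle: top-quartile cycles by ground-truth envelope mean
  env_mean <- vapply(seq_len(nrow(cyc)),
                     function(i) mean(env[cyc$start[i]:cyc$end[i]]), numeric(1))
  oracle <- env_mean >= quantile(env_mean, 0.75)
  expect_lte(sum(oracle != cyc$amplitude_ok), 2)  # boundary cycles may differ
})

test_that("an inserted phase slip is caught by the phase-reversal flag", {
  # a brief additive transient makes the analytic phase backtrack locally,
  # which is the defect the QC rule targets
  fs <- 250
  t <- (0:(fs * 8 - 1)) / fs
  x <- cos(2 * pi * 10 * t)
  mid <- 1000L
  x[mid:(mid + 12)] <- x[mid:(mid + 12)] + 1.5 * cos(2 * pi * 50 * (0:12) / fs)
  at <- instantaneous_attributes(x, fs)
  expect_lt(min(diff(at$phase_unwrapped[(mid - 20):(mid + 40)])), 0)
  cyc <- detect_cycles(at, amplitude_percentile = 0)
  bad <- cyc[cyc$start <= mid + 22 & cyc$end >= mid - 10, ]
  expect_gt(nrow(bad), 0)
  expect_true(any(!bad$no_phase_reversal))
  expect_true(all(bad$accepted == (bad$amplitude_ok & bad$controls_ok &
                                     bad$no_phase_reversal)))
  # untouched cycles far from the defect still pass
  clean <- cyc[cyc$end < mid - 250 & cyc$start > 250, ]
  expect_true(all(clean$accepted))
})

test_that("QC acceptance is monotonically non-increasing in the amplitude percentile", {
  ch <- cycle_chain_fixture()
  counts <- vapply(c(0, 25, 50, 75, 90), function(p) {
    sum(detect_cycles(ch$attr, amplitude_percentile = p)$accepted)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("too-short or degenerate inputs are handled", {
  at <- instantaneous_attributes(cos(2 * pi * 10 * (0:49) / 250), 250)
  cyc <- detect_cycles(at)  # one cycle only; edges discard it
  expect_s3_class(cyc, "cycle_table")
  expect_error(masked_sift(cos(1:50), fs = 250), "short")
})
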