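test_that("zero-asymmetry cycle train is an exact sampled cosine", {
  tr <- make_cycle_train(shape_params(f0 = 10), n_cycles = 10, fs = 250)
  expect_length(tr$signal, 250)           # 10 cycles x 25 samples
  t <- (seq_along(tr$signal) - 1) / 250
  expect_lt(max(abs(tr$signal - cos(2 * pi * 10 * t - pi / 2))), 1e-12)
  expect_true(all(abs(tr$truth$duration - 0.1) < 1e-12))
  expect_true(all(diff(tr$phase) > 0))    # unwrapped phase strictly increasing
})

test_that("peak-trough asymmetry modulates instantaneous frequency at the extrema", {
  # with a_pt = 0.3 the phase velocity at the peak (phi = 0) exceeds that at
  # the trough (phi = pi) by (1 + 0.3) / (1 - 0.3)
  tr <- make_cycle_train(shape_params(10, a_pt = 0.3), n_cycles = 30, fs = 2000)
  if_num <- diff(tr$phase) * 2000 / (2 * pi)
  ph <- tr$phase[-1] %% (2 * pi)
  at_peak <- median(if_num[abs(ph - 0) < 0.03 | abs(ph - 2 * pi) < 0.03])
  at_trough <- median(if_num[abs(ph - pi) < 0.03])
  expect_equal(at_peak / at_trough, 1.3 / 0.7, tolerance = 0.01)
})

test_that("rise-decay asymmetry matches the quadrature oracle for edge durations", {
  f0 <- 10; a_rd <- 0.2
  # rising edge: trough (phi = pi) -> peak (phi = 2*pi); falling: 0 -> pi
  t_rise <- edge_time(pi, 2 * pi, f0, a_rd = a_rd)
  t_fall <- edge_time(0, pi, f0, a_rd = a_rd)
  tr <- make_cycle_train(shape_params(f0, a_rd = a_rd), n_cycles = 50, fs = 5000)
  # measure realized edge times from the generated phase
  u <- tr$phase
  cross <- function(targets) {
    vapply(targets, function(tg) {
      i <- which(u[-1] >= tg & u[-length(u)] < tg)[1]
      (i - 1) / 5000
    }, numeric(1))
  }
  peaks <- cross(2 * pi * (5:40))
  troughs <- cross(2 * pi * (5:40) - pi)
  falls <- cross(2 * pi * (5:40) + pi)
  rise_meas <- median(peaks - troughs)
  fall_meas <- median(falls - peaks)
  expect_equal(rise_meas, t_rise, tolerance = 0.005)
  expect_equal(fall_meas, t_fall, tolerance = 0.005)
  # direction is owned by the quadrature oracle
  expect_equal(rise_meas > fall_meas, t_rise > t_fall)
})

test_that("shape invariants are enforced", {
  expect_error(shape_params(10, a_pt = 0.7, a_rd = 0.4), "phase velocity")
  expect_error(make_cycle_train(shape_params(10), n_cycles = 10, fs = 30), "fs")
})

test_that("noise-free recording has its spectral peak at the source frequency", {
  sim <- make_recording(
    list(source_spec(shape_params(10), pattern = c(1, 0.4, 0.1, 0))),
    n_channels = 4, duration = 12, fs = 250, noise_amp = 0, seed = 1
  )
  ch <- which.max(sim$truth$mixing[1, ])
  x <- sim$recording$data[ch, ]
  p <- Mod(fft(x - mean(x)))^2
  f <- seq(0, 250, length.out = length(x) + 1)[seq_along(x)]
  half <- f > 0 & f <= 125
  expect_equal(f[half][which.max(p[half])], 10, tolerance = 1 / 12 + 1e-9)
})

test_that("pure-noise recordings have log-log spectral slope -chi", {
  chi <- 1.5
  ps <- 0
  n_real <- 50
  for (s in seq_len(n_real)) {
    sim <- make_recording(list(), n_channels = 1, duration = 10, fs = 250,
                          chi = chi, noise_amp = 1, seed = 1000 + s)
    x <- sim$recording$data[1, ]
    ps <- ps + Mod(fft(x - mean(x)))^2
  }
  n <- length(x)
  f <- seq(0, 250, length.out = n + 1)[seq_len(n)]
  sel <- f >= 2 & f <= 40
  slope <- coef(lm(log10(ps[sel] / n_real) ~ log10(f[sel])))[2]
  expect_equal(unname(slope), -chi, tolerance = 0.15)
})

test_that("recordings are seeded-reproducible", {
  spec <- sim_spec(list(source_spec(shape_params(10, jitter_sd = 0.05),
                                    pattern = c(1, 0.5, 0, 0))),
                   n_channels = 4, duration = 10, fs = 250)
  a <- simulate_recording(spec, seed = 5)
  b <- simulate_recording(spec, seed = 5)
  c <- simulate_recording(spec, seed = 6)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$cycles, b$truth$cycles)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("an all-zero intervention leaves the specification unchanged", {
  spec <- sim_spec(list(source_spec(shape_params(10, a_pt = 0.1, jitter_sd = 0.02),
                                    pattern = c(1, 0))),
                   n_channels = 2)
  out <- apply_intervention(spec)
  expect_equal(out, spec)
})

test_that("power_scale = 0.5 halves alpha-band power", {
  spec <- sim_spec(list(source_spec(shape_params(10), pattern = c(1, 0.3, 0, 0))),
                   n_channels = 4, duration = 10, fs = 250, noise_amp = 0.2)
  half <- apply_intervention(spec, power_scale = 0.5)
  band_power <- function(sim) {
    x <- sim$recording$data[1, ]
    p <- Mod(fft(x - mean(x)))^2
    f <- seq(0, 250, length.out = length(x) + 1)[seq_along(x)]
    sum(p[f >= 8 & f <= 12])
  }
  ratios <- vapply(1:20, function(s) {
    band_power(simulate_recording(half, seed = s)) /
      band_power(simulate_recording(spec, seed = s))
  }, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.05)
})

test_that("tail inflation widens the realized shape-coefficient distribution", {
  sds <- matrix(NA_real_, 20, 2)
  kurts <- numeric(20)
  for (s in 1:20) {
    base <- make_cycle_train(shape_params(10, jitter_sd = 0.05),
                             n_cycles = 400, fs = 250, seed = s)
    infl <- make_cycle_train(
      shape_params(10, jitter_sd = 0.05, tail_fraction = 0.2, tail_k = 3),
      n_cycles = 400, fs = 250, seed = s
    )
    sds[s, ] <- c(sd(base$truth$a_pt), sd(infl$truth$a_pt))
    z <- infl$truth$a_pt - mean(infl$truth$a_pt)
    kurts[s] <- mean(z^4) / mean(z^2)^2 - 3
  }
  expect_gt(mean(sds[, 2] - sds[, 1]), 0)
  expect_gt(mean(kurts), 0)
})

test_that("interventions that break the shape invariants are rejected", {
  spec <- sim_spec(list(source_spec(shape_params(10, a_pt = 0.5),
                                    pattern = c(1, 0))), n_channels = 2)
  expect_error(apply_intervention(spec, a_pt_shift = 0.6), "phase velocity")
})

test_that("ground truth serializes to CSV + JSON", {
  sim <- make_recording(list(source_spec(shape_params(10), pattern = c(1, 0))),
                        n_channels = 2, duration = 10, fs = 250, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(sim$truth$cycles))
  meta <- jsonlite::read_json(paste0(csv, ".json"), simplifyVector = TRUE)
  expect_equal(meta$chi, 1.5)
})
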