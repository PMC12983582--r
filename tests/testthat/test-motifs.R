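test_that("phase alignment of a pure sinusoid gives flat IF rows", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  at <- instantaneous_attributes(cos(2 * pi * 10 * t), fs)
  cyc <- detect_cycles(at, amplitude_percentile = 0)
  m <- phase_align_if(cyc, at)
  expect_equal(ncol(m$values), 48)
  expect_equal(nrow(m$values), sum(cyc$accepted))
  row_sd <- apply(m$values, 1, sd)
  expect_true(all(row_sd < 0.01 * 10))
  expect_true(all(is.finite(m$values)))
})

test_that("injected peak-trough asymmetry is recovered in the mean IF_PA row", {
  ch <- cycle_chain_fixture()
  m <- phase_align_if(ch$cycles, ch$attr)
  expect_gt(cor(colMeans(m$values), cos(m$phase)), 0.95)
})

test_that("normalization yields group mean one and preserves shape structure", {
  ch <- cycle_chain_fixture()
  m <- phase_align_if(ch$cycles, ch$attr)
  norm <- normalize_ifpa(m)
  expect_equal(mean(norm$values), 1, tolerance = 1e-12)

  # constant matrix normalizes to all ones
  const <- m
  const$values[] <- 10
  expect_true(all(abs(normalize_ifpa(const)$values - 1) < 1e-12))

  # two groups with different mean frequencies end up overlapping at mean 1,
  # with within-group variance ratios preserved
  g1 <- planted_motif_matrix(200, sd1 = 0.6, sd2 = 0.3, seed = 51)
  g2 <- planted_motif_matrix(200, sd1 = 0.6, sd2 = 0.3, seed = 52)
  g2$values <- g2$values * 1.2  # 12 Hz-ish group
  pooled <- bind_ifpa(g1, g2)
  grp <- rep(c("a", "b"), each = 200)
  normed <- normalize_ifpa(pooled, group = grp)
  expect_equal(mean(normed$values[grp == "a", ]), 1, tolerance = 1e-12)
  expect_equal(mean(normed$values[grp == "b", ]), 1, tolerance = 1e-12)
  # normalization is a pure per-group rescaling: each group's variance is its
  # raw variance divided by the squared group mean
  for (lev in c("a", "b")) {
    raw <- pooled$values[grp == lev, ]
    expect_equal(var(as.vector(normed$values[grp == lev, ])),
                 var(as.vector(raw)) / mean(raw)^2, tolerance = 1e-10)
  }
  expect_error(normalize_ifpa(structure(list(values = matrix(c(-1, 1, 1, 1), 2),
                                             phase = c(0, 1),
                                             info = tibble::tibble(cycle = 1:2)),
                                        class = "ifpa_matrix")), "positive")
})

test_that("a rank-one matrix is explained by its first motif", {
  set.seed(53)
  centers <- seq(-pi, pi, length.out = 49)[-49] + pi / 48
  s <- rnorm(100)
  vals <- 10 + outer(s, cos(centers)) + matrix(rnorm(4800, sd = 1e-3), 100)
  m <- structure(list(values = vals, phase = centers,
                      info = tibble::tibble(cycle = 1:100)),
                 class = "ifpa_matrix")
  mm <- fit_motifs(m, n_keep = 2)
  expect_gt(mm$var_explained[1], 0.99)
})

test_that("planted orthogonal motifs are recovered in order of variance", {
  m <- planted_motif_matrix(seed = 54)
  mm <- fit_motifs(m, n_keep = 4)
  expect_gt(abs(cor(mm$loadings[, 1], cos(m$phase))), 0.9)
  expect_gt(abs(cor(mm$loadings[, 2], sin(m$phase))), 0.9)
})

test_that("PCA contract: non-increasing variance, mean-zero scores, exact reconstruction", {
  m <- planted_motif_matrix(n_cycles = 60, seed = 55)
  mm <- fit_motifs(m, n_keep = 48)
  expect_true(all(diff(mm$var_explained) <= 1e-12))
  expect_true(all(abs(colMeans(mm$scores)) < 1e-8 * apply(mm$scores, 2, sd)))
  demeaned <- scale(m$values, center = TRUE, scale = FALSE)
  recon <- mm$scores %*% t(mm$loadings)
  expect_lt(max(abs(recon - demeaned)), 1e-8)
  expect_error(fit_motifs(planted_motif_matrix(n_cycles = 1)), "at least 2")
})

test_that("motif scores shift with the correct sign under a planted shape change", {
  hits <- vapply(1:20, function(s) {
    pre <- planted_motif_matrix(150, seed = 700 + s)
    post <- planted_motif_matrix(150, seed = 900 + s)
    delta <- 0.3
    post$values <- post$values + delta * rep(cos(post$phase), each = 150)
    pooled <- bind_ifpa(pre, post)
    mm <- fit_motifs(pooled, n_keep = 2)
    co <- cor(mm$loadings, cos(pooled$phase))
    j <- which.max(abs(co))
    d <- mean(mm$scores[151:300, j]) - mean(mm$scores[1:150, j])
    d * sign(co[j]) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("split-half reliability separates planted structure from noise", {
  m <- planted_motif_matrix(seed = 56)
  rel <- split_half_reliability(m, n_splits = 100, n_components = 2, seed = 1)
  med <- glance(rel)$median
  expect_true(all(med > 0.95))

  noise <- planted_motif_matrix(seed = 57, sd1 = 0, sd2 = 0, noise_sd = 1)
  rel_n <- split_half_reliability(noise, n_splits = 100, n_components = 2, seed = 1)
  expect_true(all(glance(rel_n)$median < 0.7))

  rel2 <- split_half_reliability(m, n_splits = 100, n_components = 2, seed = 1)
  expect_identical(rel$splits, rel2$splits)  # same seed, same report
  expect_true(all(rel$splits$correlation >= -1 & rel$splits$correlation <= 1))
})

test_that("a flat IF profile reconstructs a pure cosine", {
  w <- reconstruct_waveform(rep(1, 48), n_samples = 480)
  expect_lt(max(abs(w$waveform - cos(2 * pi * w$time - pi))), 1e-6)
  expect_error(reconstruct_waveform(c(1, -1, 1)), "positive")
})

test_that("a peak-elevated IF profile narrows the peak as quadrature predicts", {
  nb <- 48
  centers <- seq(-pi, pi, length.out = nb + 1L)[-(nb + 1L)] + pi / nb
  prof <- 1 + 0.3 * exp(-(centers)^2 / 0.5)  # faster around the peak
  w <- reconstruct_waveform(prof, n_samples = 4800)
  width_meas <- mean(w$waveform > 0.5)
  width_oracle <- peak_half_width(prof)
  width_sine <- mean(reconstruct_waveform(rep(1, nb), 4800)$waveform > 0.5)
  expect_equal(width_meas, width_oracle, tolerance = 0.01)
  expect_lt(width_meas, width_sine)
})

test_that("edge-speed asymmetry survives the full round trip", {
  set.seed(58)
  a_rd <- 0.2
  tr <- make_cycle_train(shape_params(10, a_rd = a_rd), n_cycles = 300, fs = 250)
  at <- instantaneous_attributes(tr$signal, 250)
  cyc <- detect_cycles(at, amplitude_percentile = 0)
  m <- normalize_ifpa(phase_align_if(cyc, at))
  w <- reconstruct_waveform(colMeans(m$values), n_samples = 4800)
  i_peak <- which.max(w$waveform)
  i_trough <- which.min(w$waveform[1:i_peak])
  rise <- (i_peak - i_trough) / 4800
  fall <- 1 - (i_peak - 1) / 4800  # peak to final trough at cycle end
  t_rise <- edge_time(pi, 2 * pi, 10, a_rd = a_rd)
  t_fall <- edge_time(0, pi, 10, a_rd = a_rd)
  expect_equal(rise > fall, t_rise > t_fall)  # direction from the oracle
})

test_that("round-trip recovery of the injected IF profile is near-exact", {
  ch <- cycle_chain_fixture()
  m <- normalize_ifpa(phase_align_if(ch$cycles, ch$attr))
  injected <- 1 + 0.2 * cos(m$phase)
  expect_gt(cor(colMeans(m$values), injected), 0.95)
})
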