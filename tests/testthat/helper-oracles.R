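# Independent oracles used across the suite.

# Brute-force two-sample Cramer-von Mises statistic from the defining sum
# over empirical-CDF differences (Anderson 1962), O((n+m)^2).
cvm_brute_force <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  Fx <- vapply(pooled, function(v) mean(x <= v), numeric(1))
  Fy <- vapply(pooled, function(v) mean(y <= v), numeric(1))
  (n * m / N^2) * sum((Fx - Fy)^2)
}

# Quadrature oracle for edge durations of the phase-velocity law: time spent
# traversing phase interval [phi0, phi1] with velocity
# 2*pi*f0*(1 + a_pt*cos(phi) + a_rd*sin(phi)).
edge_time <- function(phi0, phi1, f0, a_pt = 0, a_rd = 0) {
  stats::integrate(function(p) 1 / (2 * pi * f0 * (1 + a_pt * cos(p) + a_rd * sin(p))),
                   phi0, phi1, rel.tol = 1e-10)$value
}

# Half-width of the waveform peak (fraction of cycle where waveform > 0.5),
# computed by direct quadrature of dt = dphi / profile.
peak_half_width <- function(profile) {
  nb <- length(profile)
  centers <- seq(-pi, pi, length.out = nb + 1L)[-(nb + 1L)] + pi / nb
  dt <- (2 * pi / nb) / profile
  sum(dt[cos(centers) > 0.5]) / sum(dt)
}

# Shared end-to-end fixture cache so several tests can reuse one sift chain.
.fixture_env <- new.env(parent = emptyenv())

cycle_chain_fixture <- function() {
  if (is.null(.fixture_env$chain)) {
    set.seed(42)
    tr <- make_cycle_train(shape_params(10, a_pt = 0.2, jitter_sd = 0.03),
                           n_cycles = 420, fs = 250)
    x <- tr$signal + 0.05 * rnorm(length(tr$signal))
    imfs <- masked_sift(x, fs = 250)
    am <- alpha_mode(imfs)
    at <- instantaneous_attributes(am$mode, fs = 250)
    cyc <- detect_cycles(at, amplitude_percentile = 25)
    .fixture_env$chain <- list(train = tr, x = x, imfs = imfs, mode = am$mode,
                               attr = at, cycles = cyc)
  }
  .fixture_env$chain
}

# Planted-motif IF_PA matrix: mean profile + two orthogonal motifs with
# unequal score variances plus small iid noise.
planted_motif_matrix <- function(n_cycles = 400, n_bins = 48, sd1 = 0.6,
                                 sd2 = 0.3, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  centers <- seq(-pi, pi, length.out = n_bins + 1L)[-(n_bins + 1L)] + pi / n_bins
  m1 <- cos(centers) / sqrt(sum(cos(centers)^2))
  m2 <- sin(centers) / sqrt(sum(sin(centers)^2))
  s1 <- rnorm(n_cycles, sd = sd1)
  s2 <- rnorm(n_cycles, sd = sd2)
  vals <- 10 + outer(s1, m1) + outer(s2, m2) +
    matrix(rnorm(n_cycles * n_bins, sd = noise_sd), n_cycles)
  structure(list(values = vals, phase = centers,
                 info = tibble::tibble(cycle = seq_len(n_cycles))),
            class = "ifpa_matrix")
}
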