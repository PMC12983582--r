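#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically read from YAML via
#' [read_pipeline_config()]) with per-stage sections. Unknown keys are
#' rejected before any stage runs; every stage default can be overridden.
#'
#' @param cfg Named list with sections `sim` (simulation spec: `n_sources`,
#'   `f0`, `a_pt`, `a_rd`, `jitter_sd`, `amplitude`, `n_channels`,
#'   `duration`, `fs`, `chi`, `noise_amp`, `intervention` with
#'   `power_scale`/`chi_delta`/`a_pt_shift`/`a_rd_shift`/`tail_fraction`/
#'   `tail_k`), `spectral` (`epoch_len`, `fmin`, `fmax`), `ssd`
#'   (`half_width`, `flank_width`, `snr_threshold`, `n_components`),
#'   `match` (`threshold`, `lobes`), `cycles` (`mask_freqs`,
#'   `amplitude_percentile`), `motifs` (`n_bins`, `n_keep`), `stats`
#'   (`alpha`, `n_boot`), plus top-level `seed` and `out_dir`.
#' @return The validated configuration, with defaults filled in.
#' @export
validate_config <- function(cfg) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    sim = list(n_sources = 2, f0 = c(10, 11), a_pt = 0.05, a_rd = 0.02,
               jitter_sd = 0.05, amplitude = c(8, 5), n_channels = 8,
               duration = 120, fs = 250, chi = 1.5, noise_amp = 1,
               intervention = list(power_scale = 1, chi_delta = 0,
                                   a_pt_shift = 0, a_rd_shift = 0,
                                   tail_fraction = 0, tail_k = 1)),
    spectral = list(epoch_len = 10, fmin = 2, fmax = 40),
    ssd = list(half_width = 2, flank_width = 2, snr_threshold = 3.87,
               n_components = NULL),
    match = list(threshold = 0.15, lobes = NULL),
    cycles = list(mask_freqs = c(120, 64, 32, 11, 7, 2),
                  amplitude_percentile = 75),
    motifs = list(n_bins = 48, n_keep = 4),
    stats = list(alpha = 0.05, n_boot = 2000)
  )
  check_keys <- function(user, def, path) {
    extra <- setdiff(names(user), names(def))
    if (length(extra) > 0) {
      abort(sprintf("Unknown configuration key(s) under %s: %s",
                    path, paste(extra, collapse = ", ")))
    }
  }
  check_keys(cfg, defaults, "top level")
  for (sec in intersect(names(cfg), names(defaults))) {
    if (is.list(defaults[[sec]]) && !is.null(cfg[[sec]])) {
      check_keys(cfg[[sec]], defaults[[sec]], sec)
      if (!is.null(cfg[[sec]]$intervention)) {
        check_keys(cfg[[sec]]$intervention, defaults$sim$intervention,
                   "sim$intervention")
      }
    }
  }
  out <- modifyList(defaults, cfg)
  if (any(out$sim$f0 >= out$sim$fs / 2)) {
    abort("Configuration invalid: source frequency at or above Nyquist.")
  }
  if (max(out$sim$f0) + out$ssd$half_width + out$ssd$flank_width >= out$sim$fs / 2) {
    abort("Configuration invalid: SSD band extends beyond Nyquist.")
  }
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file with the sections of [validate_config()].
#' @return A validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}

build_sim_spec <- function(sim) {
  f0 <- rep(sim$f0, length.out = sim$n_sources)
  a_pt <- rep(sim$a_pt, length.out = sim$n_sources)
  a_rd <- rep(sim$a_rd, length.out = sim$n_sources)
  amp <- rep(sim$amplitude, length.out = sim$n_sources)
  sources <- lapply(seq_len(sim$n_sources), function(i) {
    pattern <- rep(0, sim$n_channels)
    # smooth, source-specific sensor topography
    ch <- seq_len(sim$n_channels)
    center <- 1 + (i - 1) * (sim$n_channels - 1) / max(1, sim$n_sources - 1)
    pattern <- exp(-(ch - center)^2 / (2 * (sim$n_channels / 5)^2))
    source_spec(shape_params(f0 = f0[i], a_pt = a_pt[i], a_rd = a_rd[i],
                             jitter_sd = sim$jitter_sd),
                amplitude = amp[i], pattern = pattern)
  })
  sim_spec(sources, n_channels = sim$n_channels, duration = sim$duration,
           fs = sim$fs, chi = sim$chi, noise_amp = sim$noise_amp)
}

#' Run the full waveform-shape pipeline on a simulated pre/post session
#'
#' Orchestrates simulate, spectra, SSD, template matching, masked-EMD cycle
#' extraction, phase-aligned IF motifs, and pre/post distributional
#' statistics from a single configuration. The post-intervention recording
#' is generated from the intervention-transformed specification. Identical
#' configuration and seed give identical outputs; if `out_dir` is set, all
#' stage outputs are written as CSV/JSON with provenance columns.
#'
#' @param cfg Configuration list (see [validate_config()]); validated before
#'   any stage runs.
#' @return An object of class `pipeline_result`: list with `report`
#'   (per-stage counts and parameter echo), `iaf`, `selection`, `matches`,
#'   `cycle_summary`, `motifs` (the fitted `motif_model`), `scores`, and
#'   `stats`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  set.seed(cfg$seed)

  # -- simulate ------------------------------------------------------------
  spec_pre <- stage("simulate", build_sim_spec(cfg$sim))
  iv <- cfg$sim$intervention
  spec_post <- stage("simulate", apply_intervention(
    spec_pre, power_scale = iv$power_scale, chi_delta = iv$chi_delta,
    a_pt_shift = iv$a_pt_shift, a_rd_shift = iv$a_rd_shift,
    tail_inflation = if (iv$tail_fraction > 0) c(iv$tail_fraction, iv$tail_k)
  ))
  sims <- stage("simulate", list(
    pre = simulate_recording(spec_pre, seed = cfg$seed),
    post = simulate_recording(spec_post, seed = cfg$seed + 1L)
  ))

  # -- spectra: individual alpha frequency averaged over time points -------
  iaf_tbl <- stage("spectra", {
    models <- lapply(sims, function(s) {
      fit_spectral_model(multitaper_psd(
        s$recording, epoch_len = cfg$spectral$epoch_len,
        fmin = cfg$spectral$fmin, fmax = cfg$spectral$fmax
      ))
    })
    individual_alpha_frequency(models)
  })
  if (!iaf_tbl$present) abort("Pipeline stage `spectra` failed: no alpha peak found.")

  # -- ssd: fit on concatenated pre+post, apply per time point -------------
  band <- stage("ssd", define_bands(iaf_tbl$iaf, cfg$ssd$half_width,
                                    cfg$ssd$flank_width))
  concat <- stage("ssd", eeg_recording(
    cbind(sims$pre$recording$data, sims$post$recording$data),
    fs = cfg$sim$fs, labels = sims$pre$recording$labels
  ))
  ssd <- stage("ssd", fit_ssd(concat, band))
  n_comp <- cfg$ssd$n_components %||% max(1L, sum(ssd$lambda > median(ssd$lambda)))
  comps <- stage("ssd", lapply(sims, function(s) {
    apply_filters(s$recording, ssd, k = n_comp)
  }))
  selection <- stage("ssd", {
    sel <- select_components(
      apply_filters(concat, ssd, k = n_comp),
      snr_threshold = cfg$ssd$snr_threshold,
      epoch_len = cfg$spectral$epoch_len,
      fmin = cfg$spectral$fmin, fmax = cfg$spectral$fmax
    )
    sel
  })
  retained <- selection$component[selection$retained]
  if (length(retained) == 0) {
    abort("Pipeline stage `ssd` failed: no component passed the SNR criterion.")
  }

  # -- match patterns against the (synthetic) leadfield --------------------
  lf <- stage("match", leadfield_from_truth(sims$pre$truth, cfg$match$lobes))
  matches <- stage("match", match_components(
    ssd, lf, threshold = cfg$match$threshold, components = retained
  ))

  # -- cycles + phase-aligned IF per component x time point ----------------
  ifpa_list <- list()
  cycle_counts <- list()
  for (ci in retained) {
    mt <- matches[matches$component == ci, ]
    if (!mt$accepted) next
    for (tp in c("pre", "post")) {
      x <- comps[[tp]]$series[match(ci, comps[[tp]]$components), ]
      res <- stage("cycles", {
        imfs <- masked_sift(x, fs = cfg$sim$fs,
                            mask_freqs = cfg$cycles$mask_freqs)
        am <- alpha_mode(imfs)
        attr_i <- instantaneous_attributes(am$mode, fs = cfg$sim$fs)
        cyc <- detect_cycles(attr_i,
                             amplitude_percentile = cfg$cycles$amplitude_percentile)
        list(cyc = cyc, attr = attr_i)
      })
      cycle_counts[[sprintf("%d_%s", ci, tp)]] <-
        dplyr::mutate(glance(res$cyc), component = ci, time_point = tp,
                      .before = 1)
      ifpa_list[[sprintf("%d_%s", ci, tp)]] <- stage("motifs", phase_align_if(
        res$cyc, res$attr, n_bins = cfg$motifs$n_bins,
        info = tibble(component = ci, time_point = tp, lobe = mt$lobe)
      ))
    }
  }
  if (length(ifpa_list) == 0) {
    abort("Pipeline stage `match` failed: no component matched the leadfield.")
  }

  # -- motifs: normalize within component x time point, pooled PCA ---------
  pooled <- stage("motifs", {
    normalize_ifpa(bind_ifpa(ifpa_list), group = c("component", "time_point"))
  })
  motifs <- stage("motifs", fit_motifs(pooled, n_keep = cfg$motifs$n_keep))
  scores <- motif_scores(motifs)

  # -- stats ---------------------------------------------------------------
  stats_tbl <- stage("stats", compare_score_distributions(
    scores, time_col = "time_point", pre = "pre", post = "post",
    group_cols = "lobe", alpha = cfg$stats$alpha,
    n_boot = cfg$stats$n_boot, seed = cfg$seed
  ))

  cycle_summary <- dplyr::bind_rows(cycle_counts)
  report <- list(
    seed = cfg$seed,
    n_components_extracted = n_comp,
    n_components_retained = length(retained),
    n_components_matched = sum(matches$accepted),
    n_cycles_detected = sum(cycle_summary$n_detected),
    n_cycles_accepted = sum(cycle_summary$n_accepted),
    n_cycles_rejected = sum(cycle_summary$n_detected) -
      sum(cycle_summary$n_accepted),
    iaf = iaf_tbl$iaf,
    var_explained = head(motifs$var_explained, motifs$n_keep),
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    package_version = as.character(utils::packageVersion("wavemotif"))
  )

  result <- structure(
    list(report = report, iaf = iaf_tbl, selection = selection,
         matches = matches, cycle_summary = cycle_summary, motifs = motifs,
         scores = scores, stats = stats_tbl, band = band),
    class = "pipeline_result"
  )

  if (!is.null(cfg$out_dir)) write_pipeline_result(result, cfg$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("<pipeline_result>\n")
  cat(sprintf("  IAF: %.2f Hz; components retained/matched: %d/%d\n",
              r$iaf, r$n_components_retained, r$n_components_matched))
  cat(sprintf("  cycles detected %d, accepted %d\n",
              r$n_cycles_detected, r$n_cycles_accepted))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.1f%%", 100 * r$var_explained), collapse = ", ")))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `selection.csv`, `matches.csv`, `cycle_summary.csv`, `scores.csv`,
#' `motif_loadings.csv`, `stats.csv` and `report.json` (parameter echo plus
#' per-stage counts).
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory, created if missing.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(result$selection, "selection.csv")
  wr(result$matches, "matches.csv")
  wr(result$cycle_summary, "cycle_summary.csv")
  wr(result$scores, "scores.csv")
  wr(tidy(result$motifs), "motif_loadings.csv")
  wr(result$stats, "stats.csv")
  jsonlite::write_json(result$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
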