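# wavemotif

Cycle-level analysis of non-sinusoidal **alpha-oscillation waveform shape**
in multichannel EEG, for electrophysiologists who want to know whether an
intervention changed *how* alpha cycles are shaped, not just how much alpha
power there is.

Conventional spectral analysis assumes sinusoidal cycles and discards shape.
`wavemotif` implements the complementary pipeline:

1. **Spectral parameterization** — multitaper PSDs decomposed into an
   aperiodic component $b - \chi \log_{10} f$ plus Gaussian peaks; individual
   alpha peak frequency (IAF) and alpha SNR in dB.
2. **Spatio-spectral decomposition (SSD)** — spatial filters from the
   generalized eigenproblem $C_s w = \lambda C_n w$ (signal band IAF ± 2 Hz
   against 2 Hz flanks), Haufe patterns, and SNR-based component selection.
3. **Template matching** — components assigned to candidate sources and
   cortical lobes by absolute cosine distance
   $d = 1 - |a\cdot b|/(\lVert a\rVert\,\lVert b\rVert)$ against a
   user-supplied leadfield (accept if $d < 0.15$).
4. **Masked EMD + cycle QC** — the alpha mode isolated with mask frequencies
   120/64/32/11/7/2 Hz; per-cycle quality control (top-quartile amplitude,
   unique control points, no phase reversals).
5. **Phase-aligned IF motifs** — each cycle's instantaneous frequency
   projected onto a common 48-bin phase grid (IF_PA), normalized, and
   decomposed by PCA into waveform motifs (e.g. peak–trough width asymmetry,
   edge-speed asymmetry) with per-cycle scores and split-half reliability.
6. **Distributional statistics** — two-sample Cramér–von Mises $\omega^2$
   with asymptotic p-values, bootstrap CIs, Bonferroni correction
   ($0.05/16 = 0.003125$ for 4 motifs × 4 lobes), and 10th/90th-percentile
   tail analysis.

A first-class **synthetic-data module** generates recordings whose cycles
follow the phase-velocity law
$d\phi/dt = 2\pi f_0 (1 + a_{pt}\cos\phi + a_{rd}\sin\phi)$, mixes them into
sensors over a $1/f^\chi$ background, and applies "intervention" transforms
(power scaling, aperiodic flattening, shape shifts, tail inflation) — so the
whole chain is validated by recovering known ground truth.

## Worked example

```r
library(wavemotif)

res <- run_pipeline(list(
  seed = 7,
  sim = list(duration = 60,
             intervention = list(a_pt_shift = 0.1,
                                 tail_fraction = 0.2, tail_k = 3)),
  stats = list(n_boot = 2000)
))
res
#> <pipeline_result>
#>   IAF: 9.78 Hz; components retained/matched: 2/2
#>   cycles detected 2485, accepted 622
#>   variance explained: 65.3%, 18.9%, 12.5%, 3.0%
```

The simulated "drug" shifts the mean peak–trough coefficient by +0.1 and
draws 20% of post-intervention cycles with threefold shape jitter. In the
output, `res$motifs` holds the motif model, `res$scores` the per-cycle
scores with full provenance (component, time point, lobe, cycle), and
`res$stats` one row per lobe × motif:

```r
dplyr::select(res$stats, lobe, component, delta_mean, omega2, p_value, significant)
#> # A tibble: 8 × 6
#>   lobe         component delta_mean omega2  p_value significant
#>   <chr>        <chr>          <dbl>  <dbl>    <dbl> <lgl>
#> 1 parietal     PC1          -0.129   4.00  4.70e-10 TRUE
#> 2 parietal     PC2           0.0438  3.04  6.16e- 8 TRUE
#> 3 parietal     PC3           0.0314  1.35  3.85e- 4 TRUE
#> 4 parietal     PC4           0.0555 16.9   3.33e-11 TRUE
#> 5 sensorimotor PC1          -0.0669  1.34  4.02e- 4 TRUE
#> 6 sensorimotor PC2           0.0196  2.17  5.15e- 6 TRUE
#> 7 sensorimotor PC3           0.0172  0.787 7.84e- 3 FALSE
#> 8 sensorimotor PC4           0.0287 12.0   7.77e-15 TRUE
```

PC1 is the peak–trough width axis: its loading profile correlates −0.93
with $\cos\phi$ for this run (component polarity is a recorded convention,
so read shift direction after aligning the loading to $\cos\phi$). The
negative `delta_mean` on the $-\cos\phi$-oriented PC1 is therefore exactly
the injected *positive* peak–trough shift; `omega2` and `p_value` quantify
the distributional change, flagged against the Bonferroni threshold. `tidy()`, `glance()` and `autoplot()` methods cover the fitted
objects (`spectrum_model`, `ssd_model`, `motif_model`, `cvm_test`, cycle
tables), and every stage is exposed as a data-first function
(`multitaper_psd()`, `fit_ssd()`, `masked_sift()`, `detect_cycles()`,
`phase_align_if()`, `fit_motifs()`, `cvm_two_sample()`, ...) for use outside
the orchestrated pipeline. A thin command-line wrapper lives at
`inst/cli/wavemotif.R`.

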