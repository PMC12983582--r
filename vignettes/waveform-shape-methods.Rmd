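---
title: "Quantifying alpha-oscillation waveform shape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alpha-oscillation waveform shape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavemotif)
```

## The problem

Cortical alpha rhythms (7--14 Hz) are conventionally summarized by power,
frequency and phase, all of which treat each cycle as a sinusoid. Real alpha
cycles are not sinusoidal: peaks can be wider than troughs, rising edges can
be faster than falling edges, and these asymmetries carry physiological
information that Fourier power discards. `wavemotif` implements a cycle-level
pipeline for multichannel EEG that (1) separates alpha sources spatially,
(2) isolates the alpha mode per source, (3) describes each cycle's shape as
an instantaneous-frequency-by-phase profile, (4) compresses the profiles into
a small set of *waveform motifs* by PCA, and (5) tests whether the
distribution of per-cycle motif scores changes between a baseline and a
follow-up recording (e.g. before and after a drug).

Because scalp EEG studies of this kind usually cannot share raw data, the
package ships a synthetic-data generator that plants known shape asymmetries,
so every stage is verifiable by parameter recovery rather than by eyeballing.

## The generative model used for validation

The generator injects shape through the *phase velocity* of each cycle:

$$\frac{d\phi}{dt} = 2\pi f_0\,\bigl(1 + a_{pt}\cos\phi + a_{rd}\sin\phi\bigr),
\qquad x(t) = \cos\phi(t).$$

With the peak at $\phi = 0$ and the trough at $\phi = \pm\pi$, the cosine
term speeds the oscillation up at the peak and slows it at the trough (or
vice versa), producing peak--trough width asymmetry; the sine term modulates
the two edges differentially, producing rise--decay (edge-speed) asymmetry.
The velocity must stay positive, hence the invariant
$|a_{pt}| + |a_{rd}| < 1$. Crucially, the injected profile
$1 + a_{pt}\cos\phi + a_{rd}\sin\phi$ lives in exactly the space the pipeline
measures (instantaneous frequency as a function of instantaneous phase), so
recovery can be scored by a plain correlation. This is why shape is injected
through phase velocity rather than by warping a waveform template.

Sign conventions follow from the model rather than from intuition: with
$a_{rd} > 0$ the *descending* edge (where $\sin\phi > 0$) is traversed
faster. The package's tests score edge durations against direct quadrature of
$dt = d\phi / \text{velocity}$, which owns the direction.

Per-cycle coefficients are jittered (`jitter_sd`, default 0.05 in the
pipeline configuration) so that the PCA has genuine cycle-to-cycle shape
variance to decompose. Sources are mixed linearly into sensors through
smooth topography vectors; the background is $1/f^\chi$ noise built by
frequency-domain shaping of white Gaussian noise, independently per channel,
with an optional spatially correlated component. Amplitude is modulated by a
slow sinusoid (default 0.2 Hz, depth 0.5, uniform random phase), which gives
the amplitude-percentile cycle QC something real to select on.

"Intervention" transforms emulate pharmacological effects reported for
GABAergic modulation: alpha-power scaling, aperiodic flattening
(`chi_delta < 0`), additive shifts of the mean shape coefficients, and *tail
inflation* --- a stated fraction of cycles drawn with `k`-fold jitter SD,
which fattens the tails of the shape-score distribution without moving its
center much. That last transform is the regime in which distributional tests
outperform mean contrasts.

What the generator does **not** emulate: head-model realism (no anatomy, no
volume-conduction forward model beyond a mixing matrix), artifacts (blinks,
ECG, muscle), non-stationary aperiodic exponents, and non-sinusoidal
envelope dynamics. Passing the recovery tests therefore demonstrates that
the *measurement chain* is faithful, not that real EEG meets its
assumptions; on real data the preprocessing that this package deliberately
excludes (line noise, bad channels, ICA) still matters.

## Spectral parameterization

`multitaper_psd()` estimates power spectra on 10 s epochs with discrete
prolate (Slepian) tapers, time-half-bandwidth 4, seven tapers,
eigenvalue-weighted, averaged over epochs and channels. The tapers are
computed from the standard symmetric tridiagonal eigenproblem; for windows
longer than 640 samples they are solved on a 512-point grid, spline
interpolated and re-orthonormalized, which is ample for PSD estimation.

`fit_spectral_model()` decomposes $\log_{10}$ power into an aperiodic
component $b - \chi\log_{10} f$ (fixed mode, no knee) and up to six Gaussian
peaks, in the spirit of standard spectral-parameterization tools: a robust
aperiodic fit (points well above the initial fit are dropped and the fit
repeated), iterative peak extraction from the flattened spectrum with a
minimum height of 0.2 $\log_{10}$ units (2 dB, with dB defined as
$10\log_{10}$ power ratio) and a relative threshold of 2 SD, a joint
refit of all Gaussians, and an aperiodic refit on the peak-removed spectrum.
Peak bandwidths are constrained to 1--12 Hz. The individual alpha frequency
(IAF) is the center of the largest peak in 7--14 Hz; absence of a peak is a
value, not an error. Alpha SNR is the peak's elevation above the aperiodic
fit in dB. Channel collapsing averages linear power across channels *before*
fitting, the more stable of the two possible orders.

## Spatial separation (SSD) and template matching

Spatio-spectral decomposition maximizes signal-band power against
flanking-band power through the generalized eigenproblem
$C_s w = \lambda C_n w$. The signal band is IAF $\pm 2$ Hz with 2 Hz flanks
abutting it; covariances come from zero-phase (forward--backward)
second-order Butterworth filtering, with the noise band built by
band-passing the full flank range and band-stopping the signal band widened
by 1 Hz. Both covariances receive light shrinkage
($\gamma = 10^{-6}$), and one second is trimmed at each end before
covariance estimation to suppress filter transients. Patterns follow the
Haufe identity $A = C_s W (W^\top C_s W)^{-1}$.

Two numerical choices deserve emphasis:

* **Polarity.** Waveform shape is *not* invariant to inverting a component
  (peaks and troughs swap), but eigenvectors carry arbitrary sign. Filters
  are therefore sign-fixed so that the largest-magnitude pattern entry is
  positive. Without this convention, recovered peak--trough effects flip
  sign seed-dependently.
* **Degeneracy.** Two sources of equal band power produce (near-)equal
  generalized eigenvalues, and any rotation of their subspace is then a
  valid eigenbasis: individual mixing columns are unrecoverable in
  principle. The default simulation gives its two sources distinct RMS
  amplitudes (8 and 5 µV), which breaks the degeneracy and mirrors real
  recordings, where posterior alpha is typically stronger than
  central mu.

Components are carried forward when their eigenvalue exceeds the median
eigenvalue, then screened by spectral parameterization of the component time
series: retained components must have an in-band alpha peak and SNR
*strictly exceeding* the threshold (default 3.87 dB, exposed as a parameter
since it is a dataset-level median in origin). Spatial patterns are assigned
to candidate sources by absolute cosine distance
$d = 1 - |a\cdot b|/(\|a\|\|b\|)$ against a user-supplied leadfield
(sources × channels matrix plus per-source lobe labels); matches are
accepted below a distance of 0.15, ties broken deterministically by lowest
source index. No forward model is computed: the leadfield is a file
contract, and the synthetic module emits one from its mixing matrix.

## Masked EMD, cycles and motifs

The alpha mode is isolated by masked empirical mode decomposition with mask
frequencies 120, 64, 32, 11, 7, 2 Hz (masks at or above Nyquist are skipped
with a warning; at most six modes). At each level, a mask sinusoid with
amplitude equal to the residual's SD is added at four phases; each masked
signal is sifted once (envelope-mean subtraction with a Rilling-style
stopping rule, thresholds 0.05/0.5 with tolerance 0.05 and a 15-iteration
cap), the mask is subtracted, and the four results are averaged. The
decomposition is complete by construction --- modes plus residual equal the
input to numerical precision --- and the alpha mode is chosen as the one with
the largest alpha-band power share.

Instantaneous attributes come from the normalized Hilbert transform: the
mode is amplitude-normalized by iteratively dividing by a spline envelope
through the maxima of its absolute value (at most 3 iterations), the phase
is the argument of the analytic signal, and the instantaneous frequency (IF)
is the time derivative of unwrapped phase, lightly smoothed with a 5-sample
Savitzky--Golay window (order 2) to suppress differentiation spikes without
distorting within-cycle structure.

Cycles run between consecutive ascending zero-crossings of the signal
(phase $-\pi/2$). Quality control requires (i) mean cycle amplitude at or
above the 75th percentile of cycles in the same component and time point ---
the percentile is computed within that scope because amplitude scales are
not comparable across components; (ii) unique control points (ascending
zero, peak, descending zero, trough each crossed exactly once); and (iii)
strictly increasing unwrapped phase (no phase reversal). Cycles touching the
segment boundaries are discarded. A time-reversed segment spliced into a
sampled sinusoid does not, in fact, reverse the *analytic* phase after
envelope normalization; the reversal flag is exercised in the tests by a
brief additive transient, which does.

Accepted cycles' IF values are interpolated onto a common 48-bin phase grid
spanning $[-\pi, \pi)$ (phase-aligned IF, IF\(_{PA}\)); 48 bins oversamples
a 10 Hz cycle at 250 Hz by design and is configurable. Rows are normalized
by the grand mean IF of their component × time-point group, making profiles
dimensionless with group mean 1; normalizing per cycle instead is supported
(`group` argument) but the grouped default preserves within-group
variance structure, which is what the motif decomposition consumes. PCA is
computed once on the pooled, column-demeaned matrix (concatenated over
components, time points and --- in multi-session use --- subjects), scores are
then split by group; component signs are fixed (largest-|loading| element
positive) and recorded. Split-half reliability (default 500 random halvings)
refits the PCA per half and records sign-aligned loading correlations after
greedy matching by absolute correlation.

`reconstruct_waveform()` inverts a relative IF profile into a normalized
waveform: time per phase bin proportional to the reciprocal profile,
cumulative time mapped back to phase, $\cos\phi$ resampled on a uniform
grid covering one cycle. A flat profile reproduces a cosine to $10^{-6}$;
an elevated profile around $\phi = 0$ narrows the peak.

## Statistics

Pre/post comparisons use the rank-based two-sample Cramér--von Mises
statistic $\omega^2$ (Anderson's U-based closed form, midranks for ties).
P-values are asymptotic: the finite-sample statistic is first normalized by
its exact mean and variance onto the limiting scale, then evaluated against
the limiting distribution (a Bessel-K series). Exact enumeration over all
assignments is available for $n + m \le 20$. Bootstrap confidence intervals
resample the two groups independently with replacement (percentile
interval; the resampling scheme is a package choice, as within-group
resampling matches the within-session design). Family-wise error is
controlled by Bonferroni: with 4 motifs × 4 lobes the threshold is
$0.05/16 = 0.003125$. A tail report gives the proportions of post-scores
beyond the baseline 10th/90th percentiles, the regime where tail inflation
shows up while means barely move. Bayesian mixed-model contrasts are
deliberately out of scope; the pipeline emits descriptive pre/post summaries
plus the distributional tests.

## Problem sizes and determinism

The package's own validation uses desk-scale problems chosen to exercise
every code path with comfortable statistical margins: 8 channels at 250 Hz
and 60--120 s per time point, two sources, roughly 300--650 accepted cycles
per run after QC; 2,000 null simulations at $n = m = 100$ for type-I
calibration; 500 split-half iterations; 20 seeded end-to-end runs for the
intervention-detection rate. Every stochastic step is seeded, and an
identical configuration plus seed reproduces byte-identical outputs. The
same code runs unchanged at 64 channels / 1000 Hz.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
res <- run_pipeline(list(
  seed = 7,
  sim = list(duration = 60,
             intervention = list(a_pt_shift = 0.1,
                                 tail_fraction = 0.2, tail_k = 3)),
  stats = list(n_boot = 2000)
))
res
autoplot(res$motifs)
plot_score_distributions(res$scores, "PC1")
res$stats
```

The intervention shifts the mean peak--trough coefficient by +0.1 and draws
20% of post cycles with threefold jitter. In the fitted motif model the
peak--trough motif appears as the loading profile most correlated with
$\cos\phi$; its score distribution shifts in the injected direction and the
CvM test rejects at the Bonferroni threshold, while the tail proportions
exceed the nominal 0.10.

## Known limitations

* The IF-by-phase profile recovered through sifting and the normalized
  Hilbert transform is attenuated relative to the injected one (the shape
  *direction* and ordering are preserved; absolute coefficient magnitudes
  are not identifiable from the profile alone).
* SSD separates sources by band power contrast, not by waveform: sources
  with near-identical band power are only resolved up to a rotation.
* The masked sift assumes one oscillatory mode per mask band; closely
  spaced alpha rhythms within a single component will be merged.
* Asymptotic CvM p-values are approximate for very small samples; the exact
  branch exists for $n + m \le 20$, and the pipeline's group sizes
  (hundreds of cycles) are comfortably asymptotic.
* The synthetic leadfield contract sidesteps anatomy entirely; lobe labels
  on real data are only as good as the supplied forward model.
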