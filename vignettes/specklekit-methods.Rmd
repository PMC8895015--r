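---
title: "Methods: simulation, OSS phase retrieval, ensemble selection and damage metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, OSS phase retrieval, ensemble selection and damage metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specklekit)
```

This vignette records the model assumptions, parameter choices and
numerical decisions behind `specklekit`, in enough detail that a user can
judge what a passing test suite does — and does not — demonstrate about
real data.

## The imaging model

A compact 2-D object with electron density $\rho(\mathbf r) \ge 0$
illuminated by a coherent plane wave produces a far-field intensity
$I(\mathbf f) = |\mathcal F[\rho](\mathbf f)|^2$. Because $\rho$ is real,
$I$ is centrosymmetric (Friedel symmetry), which is what lets a beamstop
gap on one side of the centre be filled from its mirror image. All grids
place zero frequency at the centre pixel (1-based index
$\lfloor N/2\rfloor + 1$); frequencies follow the full-period convention,
so a ring at $f\ \mu m^{-1}$ corresponds to real-space period
$d = 1/f$. For a phantom with pixel size $p$ nm on an $N$-grid the
frequency increment per pattern pixel is $10^3/(Np)\ \mu m^{-1}$.

Phase retrieval is feasible because the support is constrained to a
minority of the field of view: the phantom generator enforces an
oversampling ratio above 2 per axis and rejects object fractions whose
envelope would violate it.

## The synthetic phantom and what it does (not) emulate

`make_phantom()` draws an elongated elliptical envelope (default axis
ratio 1.8, default 10% of the grid area) containing a few smooth Gaussian
blobs rescaled to span a density range (default 0.5–1.5 electrons per
pixel, 20 nm pixels) — a cartoon of a membrane-bounded organelle with
distinct high- and low-density interior regions. `diffract()`,
`add_poisson_noise()`, `apply_beamstop_and_symmetrize()`,
`crop_pattern()` and `bin_and_deconvolve()` then emulate the measurement
chain: photon-counting noise at a chosen budget, a (possibly off-centre)
rectangular stop whose shadow is partially recovered by Friedel symmetry,
and $b \times b$ detector binning followed by division of the pattern's
spectrum by the box transfer function.

Features of real experiments deliberately *not* modelled: partial
coherence, detector point-spread beyond the binning box, non-Poisson
backgrounds and readout noise, polychromaticity, an irregular beamstop
shape, and 3-D effects. Passing tests therefore demonstrate the
correctness and internal consistency of the algorithms under ideal
coherent Poisson-limited imaging, not robustness to every instrumental
imperfection.

### The radiation-damage model

`simulate_damage_series()` encodes the qualitative response of soft
biological matter to an increasing X-ray dose with the simplest model that
shows the observed trends: pixels above the support's 75th density
percentile decay multiplicatively by `high_decay` per step; pixels below
the 25th percentile gain a smooth, strictly positive blob-shaped field
whose amplitude rises linearly to `low_swell` (relative to the region's
mean) at `swell_peak_step` — transient densification, as expected from
radiation-induced aggregation of macromolecules — and afterwards the gain
halves per step while the region also starts decaying outright, so the
late series loses electrons everywhere. Defaults are 5% per step for both
rates over a four-step series with the swell peaking at step 2, giving
region-level changes of a few percent per step and a net electron loss of
several percent by the final step — the magnitude regime such experiments
report. The support never changes, matching the observation that the
overall envelope survives while internal structure degrades.

## OSS phase retrieval

Each iteration applies the Fourier magnitude projection on valid pixels
(beamstop pixels keep the iterate's modelled value — the standard
treatment, leaving those modes free), HIO feedback
$g - \beta g'$ on pixels outside the support or negative inside it
(the default constraint mode is a real non-negative object, appropriate
for electron density; a complex mode exists), and the OSS replacement of
the region outside the support by its Gaussian-filtered version with the
current stage's width.

Decisions worth recording:

* **Error metric and returned image.** The per-iteration R-factor is
  computed on the *constrained object estimate* (the magnitude-projected
  iterate with the support and positivity enforced), and the best such
  estimate is returned. The HIO driver itself retains feedback residue
  outside the support by construction, so its own R-factor never
  approaches zero even at a perfect solution; ranking the driver would
  hide convergence. Each stage restarts from the driver state at the
  best-estimate iteration of the previous stage.
* **Filter schedule.** `oss_schedule()` defaults to 2000 iterations in 10
  stages with $\sigma$ falling linearly from $N$ to $N/10$ frequency
  pixels and $\beta = 0.9$. The filtering trades a data-fidelity floor for
  noise robustness: the equilibrium R-factor grows as the filter narrows,
  which is why noiseless validation in the tests uses wide-filter
  schedules ($\sigma$ of order $4N$–$12N$, where the floor sits below
  $10^{-3}$), while noisy reconstructions use narrower ones. With all
  widths infinite the filter step is skipped entirely and the engine is
  exactly plain HIO — the suite verifies bit-for-bit agreement with an
  independently coded HIO on 32×32 instances.
* **Starting point.** Uniformly random phases on the measured magnitudes,
  from one integer seed; `run_ensemble()` uses consecutive seeds so a
  whole ensemble reproduces from one number.
* **Support.** When no support is given, `make_support()` thresholds the
  pattern's autocorrelation at 4% of its maximum and closes small gaps
  morphologically (radius 2). This is a loose but valid support — the
  autocorrelation's extent is twice the object's. A centrosymmetric
  support (e.g. a perfect ellipse) cannot break the Friedel-twin
  degeneracy, and stagnation on object/twin superpositions becomes the
  dominant failure mode; the ensemble-plus-clustering stage exists
  precisely to remove such runs.

## Ensemble selection ("convolutional features → PCA → k-means++")

Independent reconstructions agree only up to an integer translation and
the Friedel twin, so `register_reconstructions()` aligns every member to
member 1 by exhaustive twin choice and FFT cross-correlation shift
(integer shifts only; sub-pixel alignment is out of scope). The twin is
taken only when strictly better, making registration idempotent.

The feature extractor is a *fixed, seeded* bank of zero-mean unit-norm
random convolution kernels at three scales (3, 7, 15 pixels; 8 kernels
each), applied circularly, rectified, and average-pooled on a 4×4 grid —
384 features per image. Nothing is trained and nothing is downloaded, so
the embedding is fully reproducible; a learned backbone can be supplied as
a plain function if desired. This keeps the pipeline shape
(convolutional embedding, PCA to 10 components, k-means++ with `k = 4`)
while remaining self-contained. Random multi-scale convolutional features
are a standard untrained baseline and separate structurally distinct
reconstructions (twin superpositions, distorted stagnated runs) cleanly in
the planted-failure tests.

The selected cluster is the one with the lowest mean Fourier R-factor
(ties: larger cluster, then lower index) — a data-fidelity rule chosen
because it needs no ground truth; the `n_best` (default 24) lowest-R
members are re-registered to their running mean and averaged.
`baseline_cluster()` provides an average-linkage hierarchical comparator
on pairwise image correlations.

## Quality metrics

* **Shells**: 1-pixel-wide annuli about the centre out to the Nyquist
  radius; shell $j$ is centred at $(j-\tfrac12)\,w\,\Delta f$. Missing
  pixels are excluded from every shell statistic, never imputed.
* **PRTF**: shell-wise *mean of per-pixel ratios*
  $|\bar F|/\sqrt I$ (an RMS accumulation is available, and is what the
  $1/\sqrt N$ random-phase floor refers to); measured pixels with
  amplitude below $10^{-6}$ of the maximum are excluded, since dividing by
  near-zero measured amplitudes is what makes naive PRTFs blow up at high
  frequency. The accumulation choice is recorded in the curve's metadata.
  Values above 1 are possible under noise and are reported, not clipped.
* **Noise floor**: a single constant, the median shell-averaged intensity
  over the outer 10% of shells — where the power spectral density of a
  photon-limited pattern flattens to its noise level.
* **Wiener weight**: $W = S/(S+N)$ with $S = \max(\mathrm{PSD} - N, 0)$,
  zero when both vanish; the wPRTF is the pointwise product with the PRTF,
  and resolution is read at the first 1/e crossing with linear
  interpolation between bracketing shells ($d = 1/f^*$ in nm). A curve
  that never crosses returns the Nyquist-limit scale with an explicit
  `limit_reached` flag.
* **Cross-correlation**: Pearson, on raw intensities over mutually valid
  pixels (per shell, or globally per pattern pair). The flavour is
  recorded in the curve metadata so log-intensity or rank variants remain
  distinguishable if added. Shells with fewer than 3 shared pixels or
  constant values are flagged `NA`. Note that with the bright centre
  present the global statistic is dominated by the unchanging central
  speckles; computed on beamstop-masked patterns — as measured — it
  tracks the damage-sensitive speckle structure.
* **Amplitude variance**: per-pixel variance of $|F(\text{member})|$
  across registered members, shell-averaged, reported on the natural-log
  scale with raw values attached; exact zeros map to $-\infty$ and are
  counted rather than hidden.

## Damage quantification

Electron totals integrate the (unclipped) real part of the image over the
support times an explicit calibration constant (electrons per intensity
unit; synthetic default 1). Negative reconstruction values are kept to
avoid biasing totals. All fractional quantities are calibration-invariant.
Region trajectories use fixed pixel rectangles in a common registered
frame (`register_series()` reuses the shift/twin registration). For a
dose series measured with equal exposures, `add_poisson_noise()` accepts
an explicit common photon scale so that absolute intensity differences
between steps — the electron-loss signal — survive the noise step; the
pipeline sets that scale from the undamaged step.

## Problem sizes and determinism

The shipped tests and the pipeline defaults use 64–128 pixel grids,
ensembles of 4–24 members, OSS schedules of 200–900 iterations and photon
budgets around $10^6$ — sizes chosen so the full suite exercises every
path end-to-end in well under a minute while the statistical claims
(round-trip correlation > 0.99, planted-loss recovery, variance reduction
under cluster selection) hold with comfortable margins. Every stochastic
stage takes an explicit integer seed, and the pipeline derives all stage
seeds from one global seed; one config plus one seed reproduces every
report byte for byte.

## Known limitations

* Centrosymmetric supports leave the twin degeneracy unbroken; expect
  stagnated twin-superposition members in ensembles (that is what the
  clustering stage removes).
* Registration is integer-pixel; sub-pixel drifts blur averages slightly.
* The absolute electron calibration is an input, not an output; only an
  experiment-specific calibration (or a measured zero-frequency intensity)
  ties image units to electrons.
* Pattern I/O uses 32-bit float TIFF with a JSON sidecar (plus RDS for
  exact serialization); values under missing pixels are not preserved.
* Everything is 2-D.
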