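# specklekit

Coherent diffraction imaging (CDI) records only the far-field intensity of
a coherently illuminated object — the phases of the diffracted wavefield
are lost, and with them the image. When the intensity is sampled finer than
the Nyquist rate of the object's extent (*oversampling*), iterative
algorithms can recover the phases and with them a quantitative
electron-density map. For weakly scattering biological specimens the
measured speckle patterns are photon-starved and partially blocked by a
beamstop, so independent reconstruction runs disagree: some converge, some
stagnate on object/twin superpositions. `specklekit` is an R toolkit for
this whole workflow, aimed at people developing or validating CDI analysis
pipelines:

* **simulation** of oversampled speckle patterns from synthetic
  organelle-like phantoms, with Poisson photon noise, beamstop masking with
  Friedel-symmetry infill, detector binning with deconvolution of the
  binning contrast loss, and a radiation-damage dose series;
* **phase retrieval** with the oversampling-smoothness (OSS) algorithm and
  seeded ensemble restarts;
* **selection** of mutually consistent reconstructions: registration up to
  translation and Friedel twin, convolutional feature embedding, PCA,
  k-means++ clustering, and averaging of the best cluster;
* **quality metrics**: phase-retrieval transfer function (PRTF), Wiener
  weighting, wPRTF resolution at the 1/e criterion, shell amplitude
  variance, shell and global cross-correlation;
* **damage quantification**: electron totals, region density trajectories
  and lateral profiles across a registered dose series.

## The algorithms in brief

**OSS phase retrieval.** With measured amplitudes `√I(f)` on valid pixels,
support `S`, and iterate `g_k`, each iteration applies the magnitude
projection (valid pixels take the measured modulus and keep the iterate's
phase; beamstop pixels keep the iterate's own value), giving `g'_k`, then
the hybrid input-output (HIO) feedback update

    g_hio(r) = g'_k(r)                     r satisfies the constraints
               g_k(r) − β g'_k(r)          otherwise

and finally — the OSS step — replaces the region outside the support by its
Gaussian-low-pass-filtered version, `F⁻¹[ F(g_hio) · W(f) ]` with
`W(f) = exp(−f²/2σ²)`, where σ shrinks stage by stage. Wide early filters
leave HIO untouched (σ → ∞ *is* plain HIO); narrow late filters suppress
the noise-driven high-frequency content outside the support. Iterates are
ranked by the Fourier R-factor of the constrained object estimate,

    R = Σ_valid | |F(est)| − √I | / Σ_valid √I .

**PRTF and wPRTF.** With `F̄(f)` the Fourier transform of the average of
independent registered reconstructions, `PRTF(f) = ⟨ |F̄(f)| / √I(f) ⟩`
per resolution shell. Reproducible phases give 1; random phases average
toward the `1/√N` floor (0.204 for N = 24). Because noise inflates the raw
PRTF at high frequency, it is damped by the Wiener weight
`W(f) = S(f)/(S(f)+N)` built from the shell power spectral density and a
constant noise floor; the image resolution is read where the wPRTF first
drops below 1/e, as the full-period scale `d = 1/f` (nm).

## Worked example

```r
library(specklekit)
ph  <- make_phantom(seed = 2, grid_size = 128, object_fraction = 0.1)
pat <- add_poisson_noise(diffract(ph), photon_budget = 1e7, seed = 1)
pat <- apply_beamstop_and_symmetrize(pat, stop_halfwidth = 4,
                                     stop_offset = c(2, 0))
sch <- oss_schedule(600, 3, filter_sigmas = c(12, 8, 6) * 128)
ens <- run_ensemble(pat, support = ph$support, schedule = sch,
                    n_runs = 8, base_seed = 1)
sel <- cluster_ensemble(ens, k = 4, n_best = 24, seed = 1)
shells <- build_shells(dim(pat$intensity), pat$freq_per_pixel)
res <- resolution_from_curve(wprtf(prtf(sel$average, pat, shells),
                                   wiener_weight(pat, shells)))
```

which prints, step by step:

```
<phantom> 128 x 128 grid, 20 nm/pixel
  support: 1641 px (10.0% of grid), density in [0.5, 1.5] e-/px
<diffraction_pattern> 128 x 128, 0.3906 um^-1/pixel, binning 1x
  45 invalid px (0.27%), total 1.721e+06 photons on valid px
<reconstruction_set> 8 members, R-factor 0.09414 .. 0.0974
<cluster_result> method 'convre': 8 members in 4 clusters
  selected cluster 2 with 4 members
<speckle_average> of 4 members, mean R-factor 0.09534
wPRTF (1/e) resolution: 62.2 nm
correlation with ground truth: 0.9950
```

The phantom occupies 10% of the grid (oversampled 10× in area), the
off-centre beamstop leaves 45 pixels unrecoverable after symmetrization,
the eight OSS restarts all fit the noisy data to R ≈ 0.095 (the Poisson
noise floor), clustering picks a consistent 4-member subset, and the
Wiener-weighted PRTF of their average crosses 1/e at a full-period scale of
62 nm — while the average agrees with the known ground truth to correlation
0.995. A dose series is analysed the same way; see `run_pipeline()` and the
vignette, or the command line:

```sh
Rscript inst/cli/specklekit.R pipeline --seed 2 --out run1
```

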