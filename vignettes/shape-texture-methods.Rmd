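---
title: "Shape and texture in category-selective cortex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape and texture in category-selective cortex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `shapetexture`, the
assumptions behind them, the parameters that matter, and the numerical and
design decisions taken where several reasonable choices existed. The
empirical claims it makes are exactly those the test suite computes;
nothing here reports a result the package does not itself reproduce.

## 1. The scientific question and the two paradigms

An image of a face and an image of a house differ both in *shape* — the
spatial envelope, i.e. where contrast energy sits on the retina — and in
*texture* — the distribution of energy over orientations and spatial
frequencies, irrespective of position. Filtering an image in the Fourier
domain (keeping only horizontal or vertical orientations, or only low or
high spatial frequencies) changes its texture drastically while leaving its
spatial envelope largely intact. The package implements two analyses that
exploit this dissociation:

- a **multivariate** arm, which asks whether the similarity structure of
  distributed voxel patterns across the 2 × 4 condition set
  (category × filter) is better explained by a shape-based or a
  texture-based image model; and
- a **univariate adaptation** arm, which asks whether the mean regional
  response recovers from repetition suppression when the shape or the
  texture of the stimulus changes.

The two arms are sensitive to different spatial scales of the neural code
(across-voxel patterns vs within-voxel populations), which is why they can,
and in practice do, give different answers.

## 2. Stimulus filters

Filters are real gain rasters over the unshifted FFT grid, depending only
on Fourier-plane orientation or radial frequency so that they are
Hermitian-symmetric and preserve realness.

| parameter | default | units | why |
|---|---|---|---|
| orientation FWHM | 75 | degrees | wide-angle cut-off that keeps filtered images recognisable |
| low-pass half-maximum | 2 | cycles/degree | standard coarse-scale cut-off |
| high-pass half-maximum | 6 | cycles/degree | standard fine-scale cut-off |
| raster | 256 px over 10° (25.6 px/deg) | — | Nyquist 12.8 c/deg sits comfortably above the 6 c/deg cut-off |

Numerical decisions:

- "Cut-off at FWHM" is read as *gain = 0.5 at the stated value* — the only
  self-consistent reading of a full width at half maximum.
- The orientation profile is a Gaussian wrapped on the 180°-periodic
  orientation circle (sum over ±k·180° shifts, renormalised to peak 1).
  Wrapping shifts the half-maximum point by ~10⁻⁴ at FWHM 75°; tests
  account for this explicitly.
- On even-sized rasters the Nyquist row/column is shared between +f and −f;
  orientation gains are explicitly symmetrised there
  (`hermitian_symmetrize()`), which keeps the inverse transform real to
  machine precision (the residual is checked against 1e−8 and is an error
  if exceeded).
- After filtering, mean luminance is restored to mid-grey by an **additive**
  shift (preserving contrast structure, unlike a multiplicative rescale),
  then clipped to [0, 1]. The rescale-then-clip order is a deliberate
  choice; the mean-equals-0.5 contract holds exactly before clipping.

## 3. The two GIST variants

Both descriptors start from a bank of 64 Fourier-domain log-Gabor filters
(8 orientations evenly spaced over 180°, 8 centre frequencies log-spaced
from 0.25 c/deg to 80% of Nyquist). Each filter occupies a single
orientation lobe (period 360°), so the complex response is analytic and its
magnitude is the quadrature-pair energy. This rectification choice matters:
averaging the *signed* output of a band-pass filter tends to zero, so
"pixel intensities of the filtered image" are taken as energies —
standard GIST practice. Each energy map is averaged within an 8 × 8 grid:

- **shape GIST**: mean over the 64 filters, keeping the 64 grid cells
  (row-major flattening);
- **texture GIST**: mean over the 64 cells, keeping the 64 filters
  (frequency-major, orientation-minor ordering).

Both are projections of the same 64 × 64 energy table, so their grand means
agree exactly — a useful invariant the tests assert at 1e−12. Bandwidths
(1-octave radial FWHM, orientation FWHM equal to the 22.5° spacing) are
exposed as arguments; the descriptors' contracts do not depend on them.

On the synthetic stimulus set the two descriptors dissociate as intended:
same-category similarity exceeds same-filter similarity for shape GIST, and
the reverse holds for texture GIST (asserted by the acceptance suite via
block means of the two model RSMs).

## 4. Leave-one-image-out condition similarity

Model RSMs correlate each image's descriptor with the *left-out mean* of
its own condition and the full mean of every other condition, then average
within condition pairs and symmetrise. Consequences worth knowing:

- diagonal cells are not forced to 1 (they estimate within-condition
  reliability) but equal 1 exactly for duplicated vectors;
- the outer average over images makes the result invariant to image order;
- Pearson correlation is used throughout.

## 5. The multivariate arm

Per-condition voxel patterns are normalised voxel-wise (subtract each
voxel's mean across conditions), correlated with leave-one-participant-out
(LOPO) group patterns (the group mean is re-normalised the same way),
Fisher z-transformed, and regressed on the z-scored model RSMs with OLS.
Coefficients are standardised; group inference uses one-sample and paired
t tests with Cohen's d_z.

**Why the regression excludes the diagonal by default.** A LOPO diagonal
cell is the correlation of a subject's condition pattern with the group's
pattern for the *same* condition — essentially cross-subject reliability.
Both model RSMs have (near-)unit diagonals, so including the diagonal lets
reliability load on *both* regressors and inflates both coefficients; in
simulation, a pure-shape ground truth then yields a strongly positive
texture coefficient. With off-diagonal cells only, the ground truth is
recovered cleanly (texture coefficient slightly *negative*, because the
two regressors share variance). `include_diagonal = TRUE` restores the
all-cells variant for sensitivity analyses. Regressors are z-scored per
scan; collinearity beyond |r| > 0.999 is an error.

## 6. The pattern simulator and what "recovery" means

`simulate_exp1_patterns()` draws group condition patterns whose sample
correlation matrix *equals* the target mixture
β_shape·R_shape + β_tex·R_tex (unit diagonal, PSD-repaired by eigenvalue
clipping when mildly indefinite; genuinely indefinite mixtures — smallest
eigenvalue below −0.1 — fail loudly). Two constructions deserve
explanation because naive alternatives silently break group inference:

1. **Exact whitening.** The voxel noise the matrix square root is applied
   to is first empirically whitened, so the group correlation structure is
   exact at any voxel count rather than asymptotic. All participants share
   the one group pattern, so any sampling deviation in it would be a
   *fixed effect* of the replicate: identical for every subject, invisible
   to between-subject variance, and therefore converted by the t test into
   spurious significance (measured type-I error of the shape-vs-texture
   contrast: 0.53 without whitening).
2. **Finite-population subject noise.** Subject noise is centred across
   the simulated sample, so leave-one-out group estimates carry no noise
   component common to all participants — the same fixed-effect mechanism
   through a second door (type-I 0.22 with whitening alone; ≤ 0.05 with
   both). The centring makes the group test slightly conservative, which
   is the acceptable direction.

Under the default study conditions (20 subjects, 500 voxels, subject noise
SD 1 — about the same magnitude as the signal), a (0.7, 0) ground truth is
recovered (shape significant and positive, texture not significantly
positive, shape > texture) in 100 of 100 seeded replicates, and the null
(0, 0) produces no false contrast in 100 replicates; the acceptance suite
re-runs both sweeps.

## 7. Regions of interest

`flood_fill_roi()` grows a cluster from a seed (normally the map peak) by
repeatedly adding the frontier voxel with the highest z until the target
size (256 for group ROIs, 16 for peak ROIs) is reached — equivalent to
iteratively lowering a threshold while enforcing contiguity. Decisions:

- adjacency defaults to 6-connectivity (faces only), configurable to 18
  or 26; "spatially contiguous" does not pin this down, and 6 is the most
  conservative reading;
- ties (in peak finding and frontier selection) break by lexicographic
  (x, y, z) order for determinism;
- per-hemisphere operation is expressed through search masks (e.g. half
  volumes) rather than anatomical hemispheres;
- growth is peak-seeded; seeding from a supra-threshold cluster rather
  than the single peak would be a one-line change but is not the default.

ROIs nest monotonically in the target size, and on a noise-free peaked map
every member voxel outranks the best remaining frontier voxel — both
asserted against an independently re-implemented brute-force greedy oracle.

## 8. The adaptation arm

The block design (per scan): 2 categories × 3 sequences × 6 blocks, 6
images per block as three repeats of an image pair (800 ms stimulus,
200 ms ISI), 9 s fixation after each 6 s block, TR 3 s; 36 of the 216
inter-stimulus fixations are green attention targets. The neural model
responds at full gain to the first image of a pair and at
`gain × adapt_factor` to the second *unless* the pool detects the change
(shape-sensitive pools release to shape changes, texture-sensitive pools
to texture changes; no-change pairs always adapt). Amplitudes are
convolved with an amplitude-normalised single-gamma HRF (mode 6 s, scale
0.9 s) on a 0.1 s grid and sampled at the TR.

Timing conventions, made explicit because the block cycle (15 s) is not a
multiple of the epoch length (18 s): epochs are six TRs from block onset,
so each epoch's last TR overlaps the following cycle; sample *i* sits at
*i*·TR seconds, so TR 3 of a block is 9 s post-onset, where the convolved
response of a 6 s block peaks — "peak at TR 3" is therefore implemented as
a fixed-index lookup, not an argmax. Percent signal change is relative to
the run mean (the reference is otherwise unspecified); block baselines are
the epoch's own 6-TR mean, so epochs are zero-mean by construction.

The four-way repeated-measures ANOVA uses the classical within-subject
sum-of-squares decomposition (each effect tested against its own
subject-by-effect stratum, `df_den = (n−1)·df_num`, no sphericity
correction — matching the uncorrected df convention), with generalised eta
squared `SS_eff / (SS_eff + SS_subjects + ΣSS_error)`. Planned contrasts
are paired t tests for the three sequence pairings within each ROI ×
category, Benjamini–Hochberg-corrected within each ROI's family of six.

## 9. The adaptation simulator and its recovery ceiling

Defaults (chosen once, at design time, from a power analysis): preferred
gain 1, non-preferred gain 0.05, adaptation factor 0.6, per-TR noise SD 1
raw unit (~1% of the 100-unit baseline), per-subject log-normal gain
variability (SD 0.15), 24 subjects, both scans. These conditions give the
preferred-category adaptation contrasts d_z ≈ 1.5 (power ≈ 1 after
correction) while keeping the non-preferred sequence effects negligible —
the non-preferred drive is set near zero precisely so that those effects
are genuinely null at the measured scale.

One property of the full-pattern check deserves honesty: it requires
*eight* true-null comparisons (shape-change vs texture-change in each ROI,
and all three non-preferred pairings in each ROI) to all come out
non-significant at BH-adjusted α = 0.05. With the two strong positives
occupying the low ranks of each six-test family, each null faces an
effective threshold of roughly 0.025–0.05, so pure false positives bound
the expected full-pattern rate at about 0.83–0.88 *regardless of
signal-to-noise*. The acceptance suite's frozen 50-seed sweep passes at
0.88 (≥ 80% required); independent seed batches fluctuate around that
ceiling. Raising the bar would require changing the significance criterion
itself, not the generator.

## 10. What the generators do and do not emulate

Emulated: category-specific spatial envelopes with filter-sensitive
spectra; condition correlation structure as an exact model mixture;
subject-level pattern noise; repetition suppression with
attribute-specific release; HRF dynamics, block timing, attention targets;
Gaussian bump + noise statistical maps. **Not** emulated: photographic
image statistics; voxel-level spatial autocorrelation and physiological
noise; scanner drift beyond an optional baseline; motion; registration
error; anatomical hemispheres; GLM estimation from raw time series (the
multivariate arm's contract starts at per-condition patterns). Passing
tests therefore demonstrate the *pipeline's* correctness and statistical
calibration under a known forward model — not that real cortex behaves
like the simulator.

## 11. Problem sizes used by the test suite

Chosen as the package's own trade-off between fidelity and iteration
speed: descriptor fixtures use 6 images per category at 128 px
(12.8 px/deg); the design-count checks use the full 48-per-category
expansion; pattern recovery runs 100 + 100 replicates at 20 subjects × 500
voxels; adaptation recovery runs 50 replicates at 24 subjects × 2 scans ×
2 ROIs; flood-fill oracles run on 5×5×5 volumes with the full 256-voxel
case on 20³. The complete suite runs in under a minute on one core.

## 12. Known limitations

- The Gabor bandwidths and frequency range are conventions, not fitted
  values; descriptor *contrasts* are robust to them but absolute
  similarity values are not.
- Leave-one-image-out is operationalised as correlate-with-left-out-mean;
  other resampling readings would differ in small samples.
- The adaptation ANOVA offers no sphericity correction by default (the
  three-level factor makes this consequential only for marginal effects).
- The synthetic face/house generator is deliberately schematic; its
  between-category GIST separation is stronger than for photographs.
- Exp-1 style *time series* are not simulated (the design under-determines
  them); only condition patterns are.
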