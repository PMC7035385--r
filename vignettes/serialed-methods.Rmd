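---
title: "Serial electron diffraction processing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial electron diffraction processing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(serialed)
```

## The experiment this package models

Serial electron diffraction (SerialED) determines protein structures from
thousands of nanocrystals, each exposed exactly once. A scanning TEM first
records a low-dose overview image of a grid region (1024 × 1024 pixels over
an (18 µm)² field); crystals appear as compact bright features and are
located automatically. The beam — a collimated (Köhler) nanobeam of ≈110 nm
diameter and ≈0.1 nA — is then steered to each crystal and a short
dose-fractionated burst of still diffraction patterns is recorded
(10 frames × 2 ms in the conditions modeled here). At 200 kV the electron
wavelength is 0.025 Å, so the Ewald sphere is nearly flat: each still
pattern is almost a planar central section of reciprocal space, both
Friedel mates of low-order reflections are excited simultaneously, and —
the price of flatness — cell and space group cannot be inferred from a
single pattern and must be known a priori.

The package implements the full processing chain for such data, together
with a physics-based simulator that generates every input with known ground
truth, so the chain is testable end to end without a microscope:

1. **Mapping** (`find_crystals`, `make_scan_list`): feature detection on
   the overview image and serpentine scan-point ordering.
2. **Preprocessing** (`apply_corrections`, `sum_frames`, `find_center`):
   flat-field and dead-pixel correction, cumulative frame summing, and
   per-pattern beam-center refinement from the transmitted beam plus
   Friedel-pair matching.
3. **Peak finding** (`radial_background`, `find_peaks`, `hit_filter`):
   annulus-median background statistics, SNR thresholding, connected-
   component clustering, and the "more than 25 spots below ≈2.5 Å" hit
   filter.
4. **Indexing** (`index_pattern`, `predict_spots`): known-cell orientation
   determination for stills by quasi-uniform SO(3) search plus least
   squares (a deliberate, simpler stand-in for the published still
   indexers).
5. **Integration and merging** (`integrate_spots`, `scale_patterns`,
   `merge_observations`, `shell_statistics`): background-corrected pixel
   summation, per-pattern linear scaling, Monte-Carlo merging, and the
   serial-crystallography statistics block (R_split, CC1/2, CC*,
   completeness, multiplicity, Wilson B, CC* > 0.5 resolution cutoff).
6. **Damage analysis** (`shell_series`, `fit_decay`, `optimal_window`):
   per-shell exponential decay fits over the movie frames and a-posteriori
   selection of the optimal cumulative dose window.

## Geometry and conventions

Pixel coordinates are 0-based `(fast, slow)` pairs with the origin at the
center of pixel (0, 0); sub-pixel positions are real-valued. A single flat
panel normal to the beam is assumed; at λ = 0.025 Å and d ≥ 1.5 Å the
scattering angles stay below 1°, so flat-panel small-angle geometry is
exact to well below a pixel. The instrument's camera length and pixel count
are not part of the published description, so the package default is its
own choice, stated in the config rather than inferred: 1024 × 1024 pixels
of 55 µm (the pitch of the hybrid pixel detector family used for such
experiments) at 1740 mm camera length, which places the 1.55 Å shell at
the panel edge and gives ≈7.7 px spot spacing for the 103.2 Å cubic cell —
comfortably resolvable, as on the real instrument. Physical constants are
CODATA values hard-coded to ≥ 10 significant digits.

Resolution shells use equal reciprocal-volume binning (equal 1/d³
increments) unless stated; interior bin boundaries belong to the
higher-resolution shell and the outer edges are inclusive, so a range
partitions exactly.

## Crystallographic machinery

Two space groups are built in — I23 (cubic, Laue m-3) and P4₃2₁2
(tetragonal, Laue 4/mmm) — plus P1; arbitrary groups can be supplied as an
operation table. Systematic absences implement the standard reflection
conditions (I-centering: h+k+l odd absent; the 4₃ screw: (0,0,l) absent
unless l = 4n; the 2₁ axes: odd axial reflections absent). Merging is
performed in the Laue group with Friedel pairs merged. The canonical
asymmetric-unit representative of an orbit is its lexicographically
maximal member — simple, deterministic and order-independent.
`enumerate_unique` scans all integer (h,k,l) in a resolution range with
both bounds inclusive, drops absences, and counts deduplicated canonical
representatives; this count is the completeness denominator. It was
verified against an independent brute-force orbit enumeration and against
a widely used symmetry library on the same ranges.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, not conveniences.

* **Structure factors**: |F|² is drawn per unique reflection from an
  exponential (Wilson) distribution with mean `exp(-B / (2 d²))`,
  B = 12.3 Å² by default, so a Wilson regression on generated or merged
  data recovers the input B.
* **Still patterns**: for a crystal orientation R, every allowed
  reflection with excitation error |ζ| ≤ 3σ is placed at its flat-Ewald
  projected position with expected counts
  `scale · |F|² · exp(-ζ²/2σ²) · decay`, where σ (`rocking_sigma`,
  default 0.0015 Å⁻¹) is a Gaussian rocking profile standing in for
  mosaicity plus beam divergence. The partiality model is deliberately the
  simplest smooth unimodal choice: merging treats partiality by
  Monte-Carlo averaging, so only its unimodality matters.
* **Damage**: expected spot intensity decays exponentially with exposure
  time, with a per-shell 1/e time constant. The default model is a step
  function over five shells whose edges are the 1/d³ midpoints between the
  anchor resolutions 5.00, 2.33, 1.96, 1.75 and 1.61 Å, with
  τ = 14.9, 6.8, 5.9, 5.2 and 5.0 ms — the published decay times used as
  generator inputs for recovery testing. Per frame the generator uses the
  exact within-frame integral of the exponential; this differs from the
  mid-time point value by a constant factor only, so log-linear fits of
  mean intensity against frame mid-time `(i + 0.5)·Δt` recover τ without
  bias, and the sum of the 10 frames equals a single integrated 20 ms
  exposure exactly in expectation.
* **Detector**: Poisson counting noise per pixel per frame; a diffuse
  background (default 0.2 counts/px/frame — the detector class is
  essentially background-free, so this stands for residual inelastic
  scattering; the true level is not published and this is a documented
  free parameter); a multiplicative flat-field map (log-normal, 5% rms);
  dead pixels (0.2%); a transmitted-beam Gaussian disk; spot point spread
  σ = 1 px truncated at 4σ. Frame 0 is attenuated by 0.7 by default,
  emulating the shorter effective integration of the first frame, so the
  "exclude the first time point" fitting rule is exercised.
* **Overview maps**: one anisotropic Gaussian feature per crystal
  (1.5-4.5 px, i.e. ≈100-300 nm), integrated intensity proportional to the
  crystal thickness factor, on a Poisson background.
* **Seeding**: one master seed; per-crystal streams are derived by a
  counter-based linear scheme (`derive_seed`), so any subset of a dataset
  regenerates bit-identically without materializing the rest.

What the generator does **not** emulate: dynamical (multiple) scattering,
inelastic background structure, ice rings, multi-lattice patterns, or
orientation-correlated damage. Passing recovery tests therefore
demonstrates the correctness of the processing chain on kinematic,
single-lattice data — not robustness to every artefact of real
experiments.

## Processing: the decisions that matter

**Centering.** Stage 1 takes the intensity centroid of the transmitted
beam (pixels above a high quantile within the search radius, saturated
pixels excluded — hybrid pixel detectors record the direct beam, so no
beam stop is modeled). Stage 2 exploits Ewald-sphere flatness: peaks at
d > 4 Å are paired with their Friedel mates and the center is the mean of
the pair midpoints, the closed-form minimizer of Σ‖p_i + p_j − 2c‖².
Centering uses the best-SNR image, the sum of all frames, one center per
stack. On synthetic ensembles the median centering error is well below
half a pixel and unbiased.

**Peak finding.** Per-annulus robust background (median, MAD-σ, two
rejection iterations). On photon-counting data the MAD of a near-empty
background collapses to zero, so the detection threshold floors the ring σ
at `sqrt(median)` (the Poisson value) and 0.7 counts. Candidate pixels
cluster by 8-connectivity; 2-200 pixel clusters become peaks. Peak
photometry is a background-corrected box sum about the centroid rather
than a sum over threshold-exceeding pixels, which would clip the spot
tails. The hit filter reads "more than 25 spots at resolutions below
≈2.5 Å" on the low-resolution side (d ≥ 2.5 Å, configurable): low-order
spots are the robust signature of a diffracting crystal even when
high-resolution signal has decayed.

**Integration backgrounds.** The local background under a predicted spot
is the outlier-clipped mean of a square annulus (clip at 3 robust σ above
the median). A plain median — the textbook robust choice — is biased low
by several counts per box on near-empty Poisson backgrounds (the median of
Poisson(0.2) is 0 while the mean is 0.2), which adds a constant offset to
every frame and visibly flattens fitted decay curves; the clipped mean is
unbiased to ≪ 1 count while still rejecting neighbouring spots.

**Indexing.** The published still indexer is *not* re-implemented; the
package substitutes an orientation search that is simple enough to verify:

1. Observed peaks are inverted to reciprocal-space vectors g. Because a
   still measures only the on-sphere projection, the component of g along
   the beam is unknown to within the excitation window; the scoring
   therefore asks whether `B⁻¹ Rᵀ (g + t ẑ)` is near an integer triple
   for some |t| ≤ ζ_max, solving for candidate t on the largest
   component. Ignoring this one-dimensional freedom misassigns indices by
   up to ζ_max·a ≈ 0.5 of an index step for a 103 Å cell and breaks the
   search entirely.
2. A super-Fibonacci quasi-uniform quaternion grid is scored with the ~40
   innermost peaks (low-order peaks tolerate the coarsest angular step;
   the step is set so one grid step moves their fractional indices by at
   most the scoring tolerance, and the grid size is divided by the number
   of proper Laue rotations, since any solution has that many equivalent
   copies on SO(3)).
3. The ~200 best grid points are hill-climbed locally, re-ranked with a
   4× larger peak set at tight tolerance using a smooth closeness score
   (the hard match count saturates near the optimum and leaves no
   gradient), and the best few are polished by least squares.
4. Least-squares refinement minimizes pixel residuals of matched
   predictions *plus* an excitation-error penalty `(ζ/σ_ζ)²`. On a flat
   Ewald sphere, spot positions barely constrain the two out-of-plane
   rotation angles; the requirement that matched reflections be excited
   (ζ ≈ 0) is what pins them down, and with hundreds of matched spots the
   three-axis orientation error reaches a few millidegrees.
5. The candidate that explains the most observed peaks on the detector
   wins. This guards against impostor orientations from near-coincident
   lattice sections, which can match half the peaks with sub-pixel
   residuals; a solution is accepted only if it matches ≥ `min_matched`
   peaks and ≥ half of all observed peaks.

**The indexing ambiguity.** For I23 the rotation group of the cubic
lattice (order 24) is larger than the point group (order 12), so peak
positions determine the orientation only up to a two-element coset — the
classic merohedral indexing-ambiguity problem of serial crystallography.
Orientation recovery is therefore assessed modulo the lattice rotations
(`orientation_error(lattice = TRUE)`), and before merging each pattern is
brought onto a common indexing convention by
`resolve_indexing_ambiguity()`: patterns are correlated against a running
merged reference under every coset reindexing and assigned the best
alternative, with a second sweep against the full reference (the first
pattern fixes the arbitrary global convention). With a few thousand
observations per pattern the per-pattern decision is essentially
noise-free. The tetragonal case has no such ambiguity.

**Scaling and merging.** Per-pattern scaling is a linear scale only,
fitted by alternating least squares (merge → scale → re-merge, converged
at < 10⁻⁴ relative change), normalized to mean 1 — the "unity" baseline of
the reference merging tool; no per-pattern B or explicit partiality model.
Merging is the straight mean per unique reflection: still observations
scatter mainly by partiality, not counting noise, and inverse-variance
(counting) weights would drag the mean toward weakly excited observations
(a harmonic-mean bias that measurably destroys the correlation of merged
intensities with ground truth). Half sets for CC1/2/R_split are a
pseudo-random even split per reflection, deterministic in (reflection,
pattern, seed) — so re-merging the same patterns with a different dose
window reproduces the same halves and window comparisons are not
confounded by re-randomization. Merged σ is the empirical standard error
(propagated counting error for singletons). Negative merged intensities
are retained; ε-factors are ignored in the Wilson fit (≲ 1 Å² for these
groups); amplitude conversion is out of scope.

**Resolution cutoff and dose optimum.** `truncate_resolution` keeps shells
up to the last one with CC* > 0.5 before the first failure, never
re-admitting later fluctuations. `optimal_window` merges each cumulative
frame window k = 1..n and takes k* = argmax of highest-shell CC1/2 (ties
to smaller k), reporting the corresponding fluence
`(I·t/e) / (π (∅/2)²)` — with no damage, k* = n (dose only helps); with
fast high-resolution decay, k* < n.

**Damage fits.** Per-shell mean intensity of *predicted* spots (found
peaks would select against weak late frames) per single frame, fitted as
`I(t) = I₀ exp(-t/τ)` by weighted log-linear least squares (weights
∝ n_obs · mean intensity), first time point excluded by default. The fit
is exact on noise-free exponentials, invariant under intensity rescaling,
and reports "no decay detected" when the slope is non-negative within
2 SE.

## Problem sizes

All validation runs are desk-scale by design and state their sizes: 200
stills for orientation/centering/merging recovery, 100 ten-frame stacks
for decay-constant recovery, 30-stack ensembles (simulated to 2.5 Å) for
the dose-window scans, 50-crystal overview maps for mapping recall, and
6-12 pattern datasets for unit tests with a small 20 Å surrogate cell
where only plumbing is exercised. The real experiment records tens of
thousands of patterns; every statistic that improves with multiplicity
(R_split, CC1/2 at fixed shell) is therefore computed at lower
multiplicity here and is expected to be numerically worse than the
published values while following the same definitions.

## Known limitations

* Kinematic diffraction only; no dynamical scattering, so the simulator's
  intensities are more ideal than experiment.
* Single lattice per pattern; no multi-crystal deconvolution.
* The indexer requires the cell and space group a priori (as does the
  approach it models) and, with very few peaks (small cells, weak
  patterns), can accept an impostor orientation; the acceptance gate
  (fraction of peaks explained) keeps this rare under the default
  conditions but it is not impossible.
* The ambiguity resolver is reference-based and needs a handful of
  patterns with decent overlap to bootstrap its convention; isolated
  patterns stay flagged.
* Dead pixels are masked, never inpainted, in all quantitative steps;
  display-quality inpainting is out of scope.
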