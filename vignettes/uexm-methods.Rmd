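---
title: "Measuring expanded centrioles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring expanded centrioles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uexm)
```

# The measurement problem

Ultrastructure expansion microscopy (U-ExM) embeds a specimen in a swellable
gel and physically expands it about fourfold before imaging, so that a
diffraction-limited microscope resolves centriolar substructure: the
microtubule wall appears as two parallel lines in side view and as a ring in
bottom view, and the longitudinal and radial organization of centriolar
proteins can be measured in nanometres. `uexm` implements the quantitative
machinery this kind of study needs:

* line-profile extraction and **half-maximum signal-extent** detection with
  sub-pixel interpolation (lengths, diameters, relative protein positions);
* **gel expansion calibration** and correction back to biological
  dimensions;
* estimation of the procentriole length at which a marker is first
  recruited (the **appearance point**);
* **ROI fluorescence quantification** with background subtraction and
  internal-control normalization, including blind batch scoring;
* a **cyst-lineage model** of centriole inheritance under duplication
  failure;
* the exact statistics used throughout (two-sided unpaired Wilcoxon
  rank-sum, Fisher exact tests, 10/90-percentile box summaries), written
  from first principles;
* a **synthetic image generator** with known ground truth that exercises
  the whole pipeline end to end.

All positions and sizes are handled in nanometres. Quantities measured on
the expanded gel live in *expanded space*; dividing by the measured
expansion factor converts them to *corrected* (biological) space, and the
conversion is guarded so it can never be applied twice.

# Extent detection

The unit of measurement is a line profile: per-channel intensity versus
position along a user-chosen segment, averaged over a configurable line
width (wide enough to cover the centriole for longitudinal scans). Profiles
are up-sampled by an integer factor (default 3) with linear interpolation
before boundary detection, which improves localization precision without
inventing structure — the trapezoid integral is preserved exactly.

The start and end of a fluorescent signal are defined as the positions
where intensity crosses half of its peak at each extremity of the
structure. Three numerical decisions matter:

* **Baseline.** The half-maximum rule is applied to the baseline-subtracted
  peak: `threshold = baseline + half_fraction * (peak - baseline)`, with the
  baseline estimated as the median of the outer 10% of samples at each
  profile end. This makes the rule robust to a constant camera offset and
  reduces to the plain 50%-of-peak rule when the background is zero.
* **Scan direction.** Crossings are searched inward from each profile end
  and the first crossing is taken, so a noisy dip inside the structure
  cannot split the extent in two.
* **Sub-pixel localization.** Each crossing is placed by linear
  interpolation between the two bracketing samples. A dedicated acceptance
  test checks this against a brute-force 1000x-oversampled crossing finder
  to below 1e-6 nm on 500 random profiles.

A channel whose peak does not rise above the baseline yields a *no signal*
outcome distinct from an error; measurement functions record such channels
as absent rather than as zero length.

Noise statistics (used to gate and classify marker presence) are estimated
on the raw profile, never the up-sampled one: interpolated samples are
smoother than the data and understate the noise scale. The noise estimate
is the MAD over a tail window of at least four samples per end, because the
10% baseline window alone is too short on small profiles to pin the scale.

## Diameters

A radial profile through a ring crosses the wall twice. Two conventions are
provided because printed diameters do not always say which one they use:

* `peak_to_peak` (default): distance between the two wall-peak positions,
  each refined by a three-point quadratic fit — the wall-centre diameter;
* `outer_half_max`: distance between the outermost half-maximum crossings —
  the outer-edge diameter, by construction at least as large.

A profile that does not dip below the half-max threshold between two wall
crossings (e.g. a filled disc) is rejected as "fewer than two peaks" rather
than measured as a ring.

## Expansion calibration

The expansion factor of each gel is the diameter of the expanded gel disk
divided by the diameter of the biopsy punch that cut it (4 mm by
convention): a 16.0 mm disk gives factor 4.0. The electron-microscopy
reference band for the mature centriole wall diameter (200 +/- 12 nm) is
carried in the calibration object so pipelines can assert expansion
isotropy: a synthetic centriole with true biological diameter 200 nm,
rendered at factor 4 and pushed through the pipeline, must come back inside
the band.

# Marker recruitment onset

Procentrioles are sorted by whether the marker signal is present, and the
appearance point is the midpoint between the longest marker-negative and
the shortest marker-positive procentriole. When the groups interleave the
same rule is applied and an `overlap_flag` is raised rather than silently
switching estimator.

**Presence calling.** Visual presence calls are replaced by a reproducible
rule: the marker is present when its profile rises at least `k_sigma`
(default 3) noise standard deviations above the baseline, *sustained over
two consecutive raw samples*. The sustained requirement is what keeps the
rule usable at k = 3: the plain maximum of a ~100-sample noisy profile
exceeds 3 sigma several percent of the time, while a two-sample excursion
is roughly the square of that, and any real blurred marker spans many
samples.

**Uncertainty.** The midpoint estimator is built from two extreme order
statistics, for which the classical n-out-of-n bootstrap is inconsistent
and undercovers (measured ~86% for a nominal 95% interval under the
validation conditions). The interval is therefore a percentile bootstrap
over resamples of size m = n/2 (the m-out-of-n subsampling remedy for
non-regular estimators), which is mildly conservative; the subsample
fraction is exposed as a parameter.

**Detectability bias.** With a marker whose extent grows from zero at
onset, procentrioles just above onset carry signal below any detection
limit, so an appearance point estimated from *classified* presence is
biased upward toward the detectability threshold — visible in
`analysis/03_onset_estimate.R`, where the classified-presence estimate
exceeds the simulated onset while ground-truth presence recovers it. This
is a property of the appearance-point design, not of the estimator, and it
affects by-eye scoring of real data the same way.

# ROI quantification

Centriolar fluorescence is integrated either over a thresholded ROI (Otsu
threshold computed on a 64x64 window centred on the seed point — spots are
sparse in large fields, so a global Otsu would be dominated by background —
then the connected component containing the seed) or over a square of
configurable half-width. The per-pixel background is the median of an
annulus around the mask (dilation by 5 px minus dilation by 2 px) or,
alternatively, a global low percentile. Net intensity is
`integrated - background * area`; it is exactly linear in the channel
intensities. When an internal-control channel is given it is quantified on
the *same mask* with the same background method, and the reported
normalized value `net / control_net` is invariant under any common gain.

Batch quantification mirrors blind scoring: with anonymization on, the
genotype column is withheld from the measurement table and replaced by a
shuffled anonymous id whose sealed key is written separately.

# The cyst-lineage model

A goniablast carries one engaged centriole pair (2 centrioles) and divides
four times to produce a 16-cell spermatogonial cyst. Each division doubles
the centriole count if duplication is active and splits the pool as evenly
as possible (ceiling/floor) between daughters; unaffected spermatocytes
duplicate once more before meiosis, ending at 4 centrioles per cell. The
even-split rule is the minimal extension consistent with the two cases the
biology fixes (counts 1 and 2); engagement state is not modelled because
only counts are scored.

Duplication failing from the 8-cell stage leaves all 16 descendants with a
single centriole; failing from the 4-cell stage leaves, per 4-cell-stage
cell, two descendants with one centriole and two with none. A knockdown
acting between the 4- and 16-cell stages therefore produces a mixture:
with fraction `f` of final cells descending from 4-cell-stage failures,
`P(0C) = f/2` and `P(1C) = 1 - f/2`. Both mixture components are computed
by running the simulator, not hard-coded. The maximum-likelihood `f` has
the closed form `2 * n0 / (n0 + n1)`; the fitter maximizes the multinomial
likelihood numerically (grid over [0, 1] plus golden-section refinement)
and reports the closed form alongside as a check. Cells outside the 0C/1C
classes (escapers with a duplicated pair) are excluded with a warning and
counted; an optional third mixture component is deliberately not fitted by
default, to keep the model identifiable from a two-class table.

# Statistics

* **Fisher exact tests.** For 2x2 tables the two-sided p-value is the sum
  of hypergeometric probabilities of all tables with the observed margins
  that are at most as probable as the observed one (the convention of R's
  reference implementation); the doubled-one-tail convention used by some
  commercial software is available behind a flag. Larger tables are
  enumerated exactly when the total is at most 200 (multivariate
  hypergeometric probabilities over all tables with the observed margins),
  otherwise estimated by seeded Monte Carlo over `r2dtable` draws with the
  add-one rule. No display floor is ever applied to p-values.
* **Wilcoxon rank-sum.** Mid-ranks for ties. Exact mode (automatic for
  tie-free samples with at most 12 observations combined) enumerates the
  permutation distribution of the rank sum by dynamic programming over the
  integer ranks; the two-sided p-value is the probability of a rank sum at
  least as far from its null mean as observed. Otherwise a normal
  approximation with tie-corrected variance and continuity correction is
  used; its type-I error at the 5% level is checked to sit in
  [0.035, 0.065] over 2000 null replicates.
* **Box summaries.** Median, quartiles and 10th/90th percentiles with the
  type-7 linear-interpolation convention, matching box plots whose whiskers
  extend to the 10th and 90th percentiles.

# The synthetic generator

Ground-truth geometry is a hollow-cylinder wall (side view: two parallel
bars of configurable length, wall-centre diameter and wall thickness;
bottom view: an annulus) plus a proximal marker drawn as a cap (filled),
ring, or sleeve, offset relative to the proximal wall end (negative offsets
cap below the wall). Default geometry is a mature human centriole with a
proximal marker cap — biological tubulin 389.1 x 241.7 nm, marker
107.6 x 240.1 nm, wall thickness 25 nm, marker offset -20 nm — stored in
expanded space at factor 4.

Rendering and noise:

* structures are evaluated in continuous coordinates and **area-sampled**
  onto the pixel grid (closed form for 1D profiles, 3x3 subpixel pooling
  for images) before PSF convolution, so pixel quantization does not bias
  the diameter and length tests;
* the PSF is an isotropic Gaussian (sigma in expanded nm; separable
  convolution with renormalized edge kernels, so constants are preserved
  and nothing wraps around the canvas);
* noise is `Poisson(photon_scale * ideal) / photon_scale +
  Normal(0, read_noise_sd) + background_offset`: the expected image equals
  the ideal plus offset, `photon_scale = Inf` is the exact noiseless
  limit, and peak SNR on a unit-intensity structure is about
  `sqrt(photon_scale)`;
* identical seed and parameters give bit-identical output
  (`withr::with_seed` around all draws).

The growth series draws procentriole lengths uniformly over a biological
range; the marker is present iff length >= onset, with extent
`min(107.6, 0.5 * (length - onset))` nm — a deliberately simple monotone
recruitment rule, since only presence/absence versus length is constrained
by observation. Whether sub-onset markers are truly absent or merely below
detection is left open in the data; the generator exposes both readings
(`marker_model = "absent"` versus a short present marker) rather than
guessing.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: 3D structure and projection artefacts (only 2D
projected geometry is drawn), the ninefold microtubule-triplet
substructure, chromatic aberration between channels, sample drift,
non-Gaussian PSF tails, expansion anisotropy, and above all the human
steps of finding, picking and orienting centrioles. Parameter-recovery
results on synthetic data validate the *measurement machinery*, not the
biology of any particular dataset.

# Validation problem sizes

The test suite validates: half-max detection against a brute-force oracle
on 500 random profiles (< 1e-6 nm); mean corrected length on 50 noisy side
views (true 390 nm, PSF sigma 60 nm, peak SNR >= 10, factor 4) within
15 nm; mean peak-to-peak diameter on 50 rings (true 240 nm) within 10 nm,
with the outer-half-max convention never below peak-to-peak; the onset
estimator on series of 100 procentrioles (uniform 40-400 nm, onset 120 nm)
within the mean inter-sample gap, with bootstrap coverage >= 90% over 200
replicates; the three lineage outcomes exactly, and the mixture MLE against
its closed form to 1e-6; Fisher 2x2 against direct enumeration for all
margins <= 12 and Wilcoxon against full enumeration for all size splits
with m + n <= 12, plus type-I calibration over 2000 null replicates; and a
true 0.6x intensity effect (n = 30/30) detected at alpha = 0.01 through the
normalized pipeline in >= 95% of 40 seeds.

# Known limitations

* Measurement is 2D; foreshortening of tilted centrioles is not corrected.
* The half-max rule assumes a single dominant structure per profile;
  overlapping centrioles must be excluded upstream, as they are by the
  human picking step on real data.
* The appearance point inherits the detectability bias discussed above.
* The lineage model scores counts only; it cannot distinguish engaged
  pairs from two singles, and the escaper fraction is excluded rather than
  fitted.
* Image I/O stores planes as 32-bit floats normalized per image, with the
  physical calibration in a plain-text YAML sidecar; round-trips are exact
  to float32 precision, not bitwise on doubles.
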