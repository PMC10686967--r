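---
title: "Validating ALE for voxel-based morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating ALE for voxel-based morphometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alesim)
```

## The problem

Activation likelihood estimation (ALE) asks whether the peak coordinates
reported by a set of neuroimaging experiments converge in space more than
chance would allow. Each reported focus is blurred with an isotropic
Gaussian whose width reflects spatial uncertainty, the per-experiment blurs
are combined into modeled-activation (MA) maps, and the ALE score at a voxel
is the probability that at least one experiment's modeled signal lies there,

\[ \mathrm{ALE}(v) \;=\; 1 - \prod_{i=1}^{K}\bigl(1 - \mathrm{MA}_i(v)\bigr). \]

How the algorithm behaves depends on two per-experiment parameters: the
number of subjects, which tightens the kernel, and the number of reported
foci, which sets the amount of chance convergence. Structural (voxel-based
morphometry, VBM) experiments have markedly more subjects and fewer foci
than task-activation experiments, so recommendations derived from
simulations of functional data — in particular the minimum number of
experiments a meta-analysis should include — cannot be assumed to carry
over. This package rebuilds the simulation pipeline needed to re-derive
those recommendations for VBM-like data at desk scale.

## Emulating the VBM database without the database

The BrainMap VBM subset itself is access-controlled; what is public are its
printed summaries: subject counts with minimum 2, quartiles 13/20/32,
maximum 479 (after removal of >500-subject outliers), mean 30.63, SD 40.91,
and foci counts with minimum 1, quartiles 2/4/8, maximum 75, mean 6.54,
SD 7.88. `make_count_sampler()` constructs an integer distribution that
reproduces every one of these order statistics and the mean:

* the four inter-quartile bins each carry a quarter of the probability
  mass, uniformly over their integers;
* the upper-tail bin `(q75, max]` uses geometrically decaying weights whose
  rate is calibrated by root finding so the overall mean matches the target
  exactly (the rate may exceed one if a target mean ever demanded a heavy
  tail);
* a small tie mass (0.02 per interior anchor) is placed on the quartile
  values themselves. Real count data cluster on round values, and the
  printed quartiles are attained values in the database; the tie mass makes
  the sampler's quartiles sit strictly at the anchors instead of on a
  knife edge where an empirical median of a million draws would oscillate
  between adjacent integers.

The standard deviation is *induced*, not enforced: the realised values
(`r round(vbm_subject_sampler()$sd, 1)` for subjects,
`r round(vbm_foci_sampler()$sd, 1)` for foci) fall somewhat below the
database values because a geometric tail is lighter than the empirical one.
The quartiles, extremes and means — the quantities that dominate kernel
widths and chance convergence — are matched exactly; the residual SD gap is
the main known fidelity limit of the generator. Subject and foci counts are
drawn independently, mirroring the two independent draws of the original
simulation design.

For the homogeneity analysis, `stratum_range()` splits each support into
`low = [min, q25]`, `low-medium = (q25, q50]`, `high-medium = (q50, q75]`
and `high = (q75, max]` (half-open on the left; verbal descriptions of
quartile categories never fix the bin edges, so this convention is declared
once and used everywhere). The sixteen subject-by-foci category pairs
partition the joint support.

## The brain grid

All maps live on an isotropic lattice in MNI-style millimetre coordinates.
Two masks are supported:

* `load_tpm_mask()` thresholds a tissue-probability NIfTI volume at
  strictly more than 10% gray-matter probability, after nearest-neighbour
  resampling to the target voxel size (nearest neighbour so that
  interpolation cannot grow the mask);
* `make_synthetic_mask()` builds an ellipsoidal stand-in with semi-axes
  (70, 85, 72) mm, chosen once to give a ~1.8 L mask — the volume of a
  lenient gray-matter mask — without any external file. It is the canonical
  test fixture; the tissue-map route exists for users with an ICBM volume
  at hand.

Grids are aligned so that the ground-truth location (−30, −26, 58) falls
exactly on a voxel center at both 2 mm and 4 mm resolution. Foci are always
voxel centers: coordinates are "sampled from a mask", and snapping keeps
every focus identifiable with a mask voxel.

## The simulated effect

A dataset contains `n_total` experiments of which `n_signal` carry the true
effect: their first focus is replaced by the ground-truth coordinate plus
an isotropic Gaussian displacement, snapped back to the nearest mask voxel
(resampled in the rare case it leaves the mask). The displacement emulates
imperfect spatial reproducibility across experiments.

The displacement scale deserves a note, because the literature convention
is a *spread distribution* inherited from earlier simulation work rather
than an explicit value. We use a per-axis SD of 10 mm FWHM equivalent
(`10 / (2 * sqrt(2 * log(2)))` ≈ 4.25 mm). Two considerations fix this
choice. First, it matches the displacement convention of the prior
functional-data simulations this design descends from. Second, it is the
regime in which the two inference routes behave as reported: with a much
tighter spread (e.g. 2 mm) the simulated effect collapses into a
near-point source whose peak is easiest to detect by the voxel-level test,
inverting the established ordering in which cluster-level inference is the
more sensitive method; with the 10 mm FWHM spread the signal has realistic
spatial extent and cluster-level correction is the more sensitive method,
as observed on both functional and structural data. The detection vicinity
stays at ±4 mm per axis around the truth — a cluster counts as a detection
when *any* of its voxels intersects that box, which is deliberately robust
to the displacement moving cluster centers around.

## The ALE implementation

**Kernel.** Spatial uncertainty combines a between-template component
(5.7 mm) and a between-subject component (11.6 mm, scaled by
`1/sqrt(n)`), both Euclidean-distance uncertainties converted to per-axis
Gaussian SDs by dividing by `2 * sqrt(2/pi)`:
`sd(n) = sqrt(sd_t^2 + sd_s^2 / n)`. The kernel is evaluated on the voxel
lattice, truncated at 5 SD (truncation error below 1e-6) and normalised to
unit mass, so an MA value is a per-voxel probability. Within an experiment
overlapping foci combine by voxelwise *maximum*, not addition.

**Voxel-level null.** Under spatial independence an experiment contributes
to a voxel an MA value drawn from the empirical distribution of its MA map
over the mask. The null ALE distribution is computed *analytically* by
discretising each per-experiment MA histogram (bin width 1e-5 in ALE
units) and convolving the histograms through the union formula in
`(1 - MA)` space. Bin representatives are left edges, so the computed tail
probabilities never overstate significance; the cluster-forming cutoff at
voxel-level p is the smallest bin edge whose tail probability does not
exceed p. The test suite pins this machinery to exhaustive enumeration
over all voxel placements on small masks.

**FWE correction.** The maximum-statistic null redraws every experiment's
foci uniformly in the mask, recomputes the ALE map, and records the maximum
ALE score and the maximum size of connected components above the
cluster-forming cutoff. Voxel-level FWE keeps voxels whose ALE strictly
exceeds the `ceil((1 - alpha) * N)`-th order statistic of the max-ALE
samples; cluster-level FWE keeps suprathreshold clusters strictly larger
than the same order statistic of the max-cluster-size samples. Conservative
order statistics and strict exceedance break ties toward fewer false
positives; with N = 100 iterations the voxel-level route has expected
family-wise error (N + 1 − k)/(N + 1) ≈ 0.059 at the nominal 0.05, inside
the binomial tolerance used in validation. Connectivity is 26-neighbour by
default (6 and 18 available); the choice is configuration because no
convention is universal.

**Uncorrected inference** — all components above the cluster-forming cutoff
with no size filter — is carried along as a third route for the
contribution analysis, where it supplies many more clusters per dataset at
identical per-voxel mechanics.

## Outcome measures

For each analysed dataset `evaluate_dataset()` reports detection (any
significant cluster intersecting the vicinity box), the size of the largest
true cluster, the number of spurious clusters, and, per spurious cluster,
the dominant-experiment contribution profile: at each voxel the MA values
are sorted in decreasing order and the fraction

\[ f_k(v) \;=\; \frac{1 - \prod_{i \le k}\bigl(1 - \mathrm{MA}_{(i)}(v)\bigr)}
                  {\mathrm{ALE}(v)} \]

is averaged over the cluster's voxels. `f_1` is the share of the single
most dominant experiment; `f_K = 1` by construction. Profiles from
different thresholding methods use the same MA maps — the methods differ
only in which clusters they select. When pooling within a condition the
per-cluster voxel averages are averaged across clusters (each cluster
counts once); voxel-pooled and per-dataset variants differ by at most a
weighting choice and are available through the underlying records.

`derive_minimum_size()` turns a mean-`f_1`-versus-size curve into the
smallest dataset size whose mean dominant contribution falls below 50% —
the quantity behind the "include at least 23 experiments" recommendation
for cluster-level-corrected VBM meta-analyses (14 for voxel-level
correction), with low-foci strata never reaching the criterion at any
realistic size.

## Scale choices and what the tests show

A full-scale validation of this design runs hundreds of thousands of
analyses at 2 mm with 10,000 Monte-Carlo iterations each. The package makes
the faithful settings available
(`study_preset("full-main")`) but validates itself at reduced scale, with
problem sizes chosen so each check finishes in minutes on one core:

* *alpha control*: 200 pure-noise datasets at each of sizes 15, 25, 35 on
  the 4 mm synthetic mask, 100 max-statistic iterations — the family-wise
  false-positive rate of either correction should stay within binomial
  noise of 0.05. Error-rate calibration is insensitive to resolution
  because observed and null maps share whatever discretisation is used.
* *contribution thresholds*: 500 pure-noise datasets of size 23 (cFWE) and
  size 14 (vFWE) at the native 2 mm resolution. Contribution fractions are
  *not* resolution-invariant — at 4 mm each voxel holds roughly eight times
  the kernel mass, the union saturates sooner and `f_1` is biased upward by
  a few percentage points — so this analysis keeps the faithful voxel size
  and economises through the synthetic mask and iteration count instead.
* *property suites*: exhaustive-enumeration equivalence of the voxel null,
  contribution identities, monotone sensitivity in the number of true-effect
  experiments with cluster-level sensitivity at least voxel-level
  sensitivity, and the stratum orderings (more foci per experiment dilute
  the dominant contribution; more subjects concentrate it), checked on
  4-stratum subsets with uncorrected inference for cluster yield.

Monte-Carlo replicate counts put binomial noise of one to two percentage
points on rates and three to five on pooled contribution means; test
tolerances are set to those widths, not tighter.

What passing these tests does *not* show: fidelity to the real BrainMap
tail behaviour beyond the printed summaries (the geometric tail
under-disperses subject counts), anatomical realism of the ellipsoid mask
(no sulcal geometry, no mask boundary effects at real cortex), or behaviour
under correlated subject/foci counts, multiple true effects, or
between-experiment spatial correlation other than the single injected
effect. The jackknife robustness practice discussed alongside the original
study is out of scope.

## Numerical details worth knowing

* Histogram bin width 1e-5 in ALE units everywhere; conservative left-edge
  binning means thresholds can only err toward strictness.
* Kernel truncation at 5 SD; kernels are cached per subject count and
  voxel size.
* Per-dataset seeds are integer hashes of (master seed, condition index,
  replicate index), so results are independent of scheduling and worker
  count, and checkpointed conditions can be resumed byte-identically.
* Degenerate inputs fail fast: empty masks, empty draw requests,
  non-monotone anchors, infeasible mean targets, `n_signal > n_total`,
  probabilities outside (0, 1).
* `alpha = 0.05`, cluster-forming `p = 0.001`, vicinity ±4 mm, and the
  26-neighbour connectivity are defaults mirroring the validated study;
  all are configurable through `study_config()`.
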