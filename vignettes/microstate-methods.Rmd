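---
title: "EEG microstate analysis with microstatr: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis with microstatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

## The microstate model

Resting-state EEG does not wander continuously through topography space:
for stretches of roughly 60-120 ms the spatial distribution of scalp
potential stays quasi-stable, then switches abruptly to another
configuration. These quasi-stable topographies -- *microstates* -- are
classically summarized by a small set of template maps (four in much of the
literature, labeled A-D) plus a per-sample labeling of the recording.

`microstatr` estimates this model in the standard two stages:

1. **Template extraction.** At the local maxima of the global field power
   (GFP, the spatial standard deviation of the average-referenced sample --
   moments of highest topographic signal-to-noise), a *polarity-invariant
   modified k-means* clusters the peak topographies: each peak is assigned
   to the template with the highest squared spatial correlation, and each
   template is re-estimated as the dominant spatial pattern (the first
   principal component) of its assigned peaks. Polarity is ignored
   throughout because the generating dipole configuration reverses sign
   within an oscillatory cycle. Clustering is run per subject first, and
   the pooled subject templates are clustered again at the group level;
   group maps correlated at `merge_threshold = 0.80` or higher are merged.
2. **Back-fitting.** Every sample of every recording is labeled with the
   template of highest absolute spatial correlation, subject to a
   correlation threshold (default 0.5; weaker samples stay unassigned) and
   a temporal smoothing step. Per subject and map, four parameters are
   extracted: GEV (percent of GFP-weighted variance explained), mean
   duration (ms), time coverage (percent), and occurrence (runs/s).

The objective maximized by the clustering is the global explained variance

$$\mathrm{GEV} = \frac{\sum_t \big(\mathrm{GFP}_t \, r_t\big)^2}{\sum_t \mathrm{GFP}_t^2},$$

where $r_t$ is the spatial correlation between sample $t$ and its assigned
template. Both k-means steps monotonically increase GEV, so any fixed point
is a local optimum; the package verifies against brute-force partition
enumeration on tiny instances that the best-of-restarts solution attains
the global optimum there.

## Choosing the number of maps

The number of clusters is chosen by a median vote over five internal
validity criteria computed on the same clustering runs: a cross-validation
criterion (predictive residual variance with the $((C-1)/(C-1-k))^2$
correction), Calinski-Harabasz, Krzanowski-Lai, mean silhouette on the
polarity-invariant correlation distance $1-|r|$, and Davies-Bouldin. Each
criterion nominates its optimal $k$; the reported $k$ is the lower median
of the nominations (ties resolve toward fewer maps). The exact metric set
behind published "meta-criterion" implementations is not public, so the
composition here is fixed, documented, and auditable: the raw criterion
values for every candidate $k$ are returned for inspection. Degenerate
peak sets (a single spatial pattern) short-circuit to the smallest
candidate $k$.

## Temporal smoothing

The label smoother is a penalized windowed relabeling: the score of map
$m$ at sample $t$ is the GFP$^2$-weighted squared-correlation support summed
over $\pm$`half_window` samples, plus `strength` (scaled by the mean
GFP$^2$) times the number of neighbors in the window currently labeled $m$.
Updates run as red-black (odd/even) half-sweeps to a fixed point; a fully
synchronous update can oscillate on pathological alternating input, while
alternate-site sweeps converge. `half_window = 0, strength = 0` is exactly
the identity. Unassigned samples are never relabeled and break runs; this
choice (rather than re-thresholding after smoothing) keeps the threshold
contract exact. Equivalence with any particular legacy implementation is
not claimed; the parameters have the conventional meaning (window half-size
3 samples, strength 10 by default).

Two bookkeeping choices are deliberate and documented rather than
universal: runs truncated at the recording edges count toward duration and
occurrence, and coverage denominators use *total* samples, so coverages sum
to less than 100% exactly when unassigned samples exist. On segmentations
without unassigned samples the identity
`coverage = occurrence * mean_duration / 10` holds to floating-point
precision and is enforced by tests.

## Transition structure

Transitions are run-level events: consecutive runs with different labels
contribute one count, transitions into or out of unassigned stretches are
dropped, and the diagonal is structurally zero. Observed row-conditional
probabilities are divided by the probabilities expected under independence,
with self-transitions excluded from the normalizing pool:
$E_{ij} = f_j / \sum_{m \ne i} f_m$, with $f$ the per-map *run counts*.
Using run counts (not sample coverage) matches the event-level nature of
transitions; excluding the self-pool avoids a systematic downward bias in
the expected probabilities. Both choices are configurable inputs to
`normalized_transitions()` in the sense that any frequency vector can be
supplied.

## Inference

* Group differences in microstate parameters use Mann-Whitney U tests with
  midrank ties, exact enumeration when $n_1 n_2 \le 400$ without ties, and
  Cliff's delta $\delta = 2U/(n_1 n_2) - 1$ oriented to the first-listed
  group.
* Pooled-variance two-sample t tests (df $= n_1+n_2-2$) with Cohen's d are
  used for transition ratios and for recomputing printed demographic
  statistics from summary values.
* Multiplicity over the correlated microstate variables is controlled by
  the Li-Ji effective number of tests: eigenvalues $\lambda_i$ of the
  variables' correlation matrix give
  $M_\mathrm{eff} = \sum_i \big(I(|\lambda_i| \ge 1) + (|\lambda_i| -
  \lfloor |\lambda_i| \rfloor)\big)$ and the Sidak-adjusted per-test level
  $\alpha_\mathrm{adj} = 1-(1-\alpha)^{1/M_\mathrm{eff}}$. The package
  recomputes the adjusted level from its own data rather than hard-coding
  any published threshold; with $M_\mathrm{eff} = 6$ at $\alpha = 0.05$
  the adjusted level evaluates to about 0.009. Rejection is for p *below*
  the adjusted level (statements to the contrary in print are treated as a
  typographical slip).
* Topographic group differences use TANOVA: subject maps are scaled to
  unit GFP, group means are formed and normalized again, and the global map
  dissimilarity (root mean squared channel difference) is referenced to its
  permutation distribution over group labels. The observed statistic is
  counted in both numerator and denominator, so p is never zero.
* Correlations (Pearson or Spearman) carry percentile bootstrap confidence
  intervals (5000 resamples by default); families of correlations are
  corrected with Benjamini-Hochberg FDR.

## The synthetic-data generator

Because the package is validated without access to clinical recordings,
`simulate_cohort()` plants known microstate structure:

* **State dynamics.** A semi-Markov chain: per-map dwell times are
  geometric on samples with configurable means (default 80 ms, within the
  canonical 60-120 ms range), successors drawn from a row-stochastic
  transition matrix with zero diagonal (default uniform). Geometric dwell
  is an assumption of convenience -- it is the memoryless choice consistent
  with first-order Markov transition analysis -- not an empirical claim
  about real dwell distributions.
* **Signal.** The active template is scaled by a rectified 10 Hz sinusoid
  plus a constant floor, so GFP peaks arrive at a realistic ~20/s rate.
  Template polarity flips at each envelope trough with probability
  `flip_prob = 0.8`. A pure alpha oscillation flips polarity at *every*
  trough; retaining most of that half-cycle coherence preserves a genuine
  8-14 Hz spectral peak. (Fully random flipping at probability 0.5 makes
  adjacent half-cycles independent, which provably spreads the alpha line
  into a broad 0-20 Hz hump -- the signed-hump process has power spectrum
  proportional to the squared half-sine pulse transform, maximal near DC --
  so that setting is offered but not the default.)
* **Noise.** Spatially correlated Gaussian noise (squared-exponential
  kernel over electrode distances, mildly colored in time with an AR(1)
  coefficient of 0.6 for a soft 1/f tilt) plus 40% white sensor noise,
  scaled so the state-signal-to-noise RMS ratio equals `snr` exactly
  (default 4).
* **Cohort design.** Two groups (18 subjects each by default, matching the
  emulated study design). The patient-like group B receives a 1.3x longer
  mean dwell on map C and a 1.5x inflated B-to-C transition probability
  (row renormalized); each subject additionally gets log-normal jitter
  (sd 0.1) on dwell means and mild jitter on transition rows as
  between-subject variability. These effect sizes are fixed generator
  defaults, not tuning knobs.
* **Montage and templates.** Electrodes lie on a deterministic Fibonacci
  cap (64 by default -- a desk-scale stand-in for high-density nets; the
  count is a parameter). Templates are single-dipole potential fields with
  jittered canonical A-D orientations, regenerated until all pairwise
  absolute correlations are below 0.8 so that template similarity never
  triggers merging by construction.

What the generator does **not** emulate: biophysical volume conduction
through a realistic head model, eye/muscle/cardiac artifacts, bad channels,
non-stationarities (drowsiness, arousal), or heavy-tailed dwell
distributions. Passing the recovery suites therefore demonstrates the
*correctness of the estimation machinery under the stated generative
model*, not robustness to everything real EEG can do.

## Numerical choices

* Filters: second-order Butterworth band-pass (1-40 Hz default) and an RBJ
  biquad notch (quality factor 30), both applied forward-backward.
  Zero-phase filtering preserves microstate timing at the cost of slight
  non-causality; for segmentation analysis this is the right trade.
* GFP uses the population (1/C) normalization; only relative values matter
  downstream. GFP peak plateaus resolve to their leftmost sample, so peak
  extraction is deterministic.
* k-means convergence: GEV improvement below 1e-6 or 200 iterations;
  empty clusters are re-seeded from the worst-fit peak. Restart
  initializations sample peaks without replacement; when there are fewer
  distinct k-subsets than requested restarts, all subsets are enumerated,
  making tiny-instance behavior exhaustive and reproducible.
* Template sign is fixed by making the largest-magnitude channel positive;
  assignment ties go to the lower map index. All random stages accept a
  seed and restore the caller's RNG state.
* Spectra: one Hanning taper over the whole record, zero-padded so the
  frequency grid spacing is at most 0.034 Hz, scaled so that total
  one-sided power equals the tapered time-domain mean square. The beta
  split by k-means standardizes log power before clustering; raw 1/f power
  would otherwise dominate the distance.

## Problem sizes used by the validation suites

The test suite exercises the full recovery path at 36 subjects, 64
channels, 60 s per subject, snr 4 -- with subject-level clustering fixed at
k = 5 (15 restarts) and group-level selection over k = 1..8 (40 restarts),
a desk-scale configuration the package documents as sufficient for
template recovery at $|r| \ge 0.95$. TANOVA calibration uses 1000 null
simulations at 200 permutations; bootstrap coverage uses 300 replicates at
250 resamples; planted-effect recovery uses 20 cohort replicates of 30 s
recordings. Defaults in `default_config()` remain at the full analysis
scale (300 restarts, k up to 12, 5000 permutations/resamples, 240 s).

## Known limitations

* Subject-level map counts vary when selected per subject; pooling
  templates across subjects with different k is standard but means the
  group-level input is not balanced per subject.
* The meta-criterion's five-member composition is principled but not the
  only defensible choice; on data without clear cluster structure different
  compositions can nominate different k.
* The smoother is a documented algorithm with conventional parameters, not
  a bit-exact reimplementation of any legacy tool.
* EDF support covers the plain continuous 16-bit subset only (integer
  sampling rates, one-second records).
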