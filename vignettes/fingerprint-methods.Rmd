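---
title: "Methods: the TLE connectome fingerprint and its synthetic test bed"
author: "tleFingerprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TLE connectome fingerprint and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tleFingerprint)
```

## The model

Mesial temporal lobe epilepsy (TLE) leaves a distributed signature across
functional and structural brain networks. The fingerprint approach
assumes that patients who become seizure-free after mesial temporal
surgery are *homogeneous* in connectome space — they share a
characteristic connectivity profile — while patients whose seizures recur
deviate from that profile in heterogeneous ways. Scoring a prospective
patient therefore reduces to measuring distance from the seizure-free
profile rather than classifying against a (heterogeneous) recurrence
class.

The pipeline has five stages.

### 1. Age-normative correction

Connectivity changes with age, so raw edges are not comparable across
subjects. For every one of the `n(n-1)/2` unique edges we fit ordinary
least squares of edge value on age across the healthy-control cohort and
keep the intercept, slope, and residual RMSE (residual df `n - 2`,
matching the two fitted parameters). A subject's edge is then expressed
as

$$z = \frac{t(x) - a - b \cdot \mathrm{age}}{\mathrm{RMSE}}$$

in *standard deviations from age-matched control*. The transform $t$ is
the identity for FC (Fisher-z partial correlations are already
approximately Gaussian) and $t(x) = \log(x + 1)$ for SC: volume-scaled
streamline counts are heavy-tailed and become approximately Gaussian
after a log, and the `+1` keeps absent connections (zero streamlines)
finite while preserving monotonicity. The transform is applied *after*
volume scaling. Degenerate fits (fewer than 3 controls, constant ages, an
edge with numerically zero residual variance) are errors naming the edge,
never silent.

Two readings of "scaled by the inverse of the two node volumes" are
possible (product or sum of volumes); `countsToSC()` uses the product
$x_{ij} = \mathrm{counts}_{ij} / (v_i v_j)$, the most literal one.

### 2. Focus orientation

Left and right TLE are pooled by relabelling hemispheres relative to the
seizure focus. The left hemisphere is the reference frame: a left-focus
subject's matrix is unchanged (relabelled only), a right-focus subject's
matrix has every homologue pair's row and column swapped. The transform
permutes values consistently, preserves the edge multiset and symmetry,
and is an involution. The midline brainstem is retained in matrices but
belongs to no lobe and is never treated as ipsilateral.

### 3. Profile reduction

With the connectome in normative units and focus-oriented frame, each
ipsilateral node receives a weighted degree over the 14 nodes of interest
(NOI) — bilateral middle cingulate, precuneus, thalamus, anterior and
posterior insula, anterior and posterior hippocampus:

$$\mathrm{wdeg}(i) = w_{\mathrm{ipsi}} \sum_{j \in \mathrm{NOI}_{\mathrm{ipsi}}, j \neq i} C_{ij} + w_{\mathrm{contra}} \sum_{j \in \mathrm{NOI}_{\mathrm{contra}}} C_{ij},$$

with the 2:1 weighting ($w_{\mathrm{ipsi}} = 2$, $w_{\mathrm{contra}} =
1$) as default. The diagonal never contributes. NOI nodes are themselves
ipsilateral nodes and contribute to their own lobe's average (no stated
exclusion exists, and removing them would leave the subcortical lobe
dominated by filler regions); self-edges are excluded. Weighted degrees
are averaged over the six ipsilateral lobes — prefrontal, parietal,
occipital, temporal, motor/somatosensory, subcortical, in that fixed
order — and the FC and SC 6-vectors concatenate into the 12-measure
connectivity profile. Zero is the age-matched-control reference.

Lobe membership comes solely from the atlas table. The fixture atlas
assigns hippocampal composites and both insulae to temporal, thalamus to
subcortical, middle cingulate to prefrontal and precuneus to parietal;
any other assignment can be supplied by editing the atlas file.

### 4. Fingerprint construction

Nine model subjects are too few to estimate a 6-dimensional covariance
per modality, so the model group is bootstrap-expanded: 10 bootstrap
samples of six subjects (with replacement — the standard bootstrap
reading; without-replacement subsampling is a config option), and from
each sample four subsample connectomes with edge values $m + u s$, where
$m, s$ are the per-edge sample mean and SD and $u$ is drawn per edge and
per subsample uniformly on $[-4, 4]$ ("up to four times the standard
deviation"). The phrase admits several readings (one multiplier per
subsample, a fixed $\pm1..4$ grid); the per-edge uniform multiplier is
the least structured one consistent with "up to", and the alternatives
would only change the spread, not the mean, of the expanded profiles. FC
and SC share the subject sample within a bootstrap but draw independent
multipliers. The expansion operates at the edge level *before* profile
reduction, and the fingerprint's Euclidean reference is the mean of the
40 expanded profiles (not the 9 subjects). The expansion is fully
reproducible from its seed.

### 5. Distance scoring

Per modality, a scored profile $p$ yields the Euclidean distance
$\lVert p - \mu \rVert$ and the Mahalanobis distance
$\sqrt{(p-\mu)^\top \Sigma^{-1} (p-\mu)}$ with $\mu, \Sigma$ the mean and
sample covariance of the 40 model profiles; the modality distance is
their *sum*, kept without rescaling despite the different natural units
— fidelity to the method as defined — and the total distance is
$\sqrt{\mathrm{FC}^2 + \mathrm{SC}^2}$. Euclidean captures magnitude of
deviation, Mahalanobis pattern deviation; their sum reflects that either
kind of dissimilarity counts against fingerprint membership.

## Evaluation statistics

* **Outcome groups.** Kruskal–Wallis across the four 1-year Engel groups
  (Ia, Ib-d, II, III–IV) on total distance, then all six pairwise
  Wilcoxon rank-sum tests with Bonferroni factor 6; the same battery runs
  on fc-only, sc-only, Euclidean-only and Mahalanobis-only variants (the
  latter two combine modalities Pythagorean-style, mirroring total
  distance, since the method defines no other combination for them).
  `stats::wilcox.test` supplies exact p-values for small tie-free groups
  and the tie-corrected normal approximation otherwise. Subjects flagged
  `exclude_from_group_stats` are removed before any statistic.
* **ROC.** The full curve (via pROC), trapezoidal AUC, and the
  Youden-optimal operating point; ties in Youden's J break toward higher
  specificity, since the clinical cost asymmetry (denying surgery to a
  responder) argues for specificity when sensitivity is equal.
* **Random-node permutation null.** Per iteration, `k = 14` nodes are
  drawn uniformly from all 117 (so drawn sets are usually
  hemisphere-unbalanced); each drawn node is weighted by its hemisphere
  relative to focus — ipsilateral 2, contralateral or midline 1 — the
  closest consistent generalization of the 2:1 scheme to arbitrary sets.
  The fingerprint is rebuilt from the same expanded connectomes, subjects
  are ranked ascending by total distance with average ranks for ties, and
  the unfavourable subjects' ranks are summed. The observed percentile
  uses the add-one estimator $(1 + \#\{\mathrm{null} \ge
  \mathrm{obs}\})/(n_{\mathrm{iter}} + 1)$, which cannot return a zero
  p-value from a finite null.
* **Clinical screen.** Total distance against each continuous covariate
  by Spearman correlation and each binary covariate by rank-sum,
  Bonferroni over the covariate count; plus a 12-measure-by-covariate
  matrix at uncorrected 0.05 with direction flags.

## The synthetic cohort generator

`simulateCohort()` emulates the study's cohort structure: 85 controls and
52 patients split 9 (model, Engel Ia) / 5 (test, one unfavourable) / 38
(left-out, outcomes 15/11/5/7 across Ia/Ib-d/II/III–IV), ages uniform on
18–71, seizure sides alternating left/right.

* **Controls.** FC edges: per-edge baseline ~ N(0.2, 0.3) on the Fisher-z
  scale, age slope ~ N(0, 0.003)/year, noise SD 0.15. SC edges: on the
  log1p scale of volume-scaled weights, baseline ~ N(3, 1.2) floored at
  1, slope ~ N(0, 0.004), noise SD 0.3, mapped through `expm1` (floored
  at zero) to nonnegative continuous streamline weights — SIFT2-style
  weighting is continuous, and continuous weights keep the log-linear
  generative model exact. The floor at 1 keeps every edge's control
  distribution clear of the zero clamp so no normative fit degenerates by
  construction. These magnitudes are plausible-scale choices; the method
  itself only constrains the transforms, and the normative correction
  absorbs affine rescalings.
* **Patients.** All patients share a mild common deviation (default 0.5
  normative SD, negative-going, on all 12 measures) — the seizure-free
  TLE profile. Unfavourable patients additionally deviate on configured
  measures (default: 3 normative SD on fc/sc temporal and subcortical)
  on edges incident to the ipsilateral NOI. Each unfavourable subject is
  randomly FC- or SC-dominant (dominant modality scaled 1.5, the other
  0.5), mirroring the observed heterogeneity of recurrence. Deviations
  are planted in the subject's focus-oriented frame and homologue-mapped
  to their anatomical side.
* **Exact effect placement.** The six lobe patterns overlap on
  NOI-incident edges, so scaling each pattern alone would cross-talk
  between measures. The generator instead solves a 6×6 linear response
  system per modality so the planted edge shift moves each lobe measure
  by exactly its target in expectation.
* **Ground truth.** The returned object (and `ground_truth.json`)
  records the config, every per-edge baseline and slope, and each
  subject's group, side, outcome and modality dominance; together with
  the seed this reproduces every planted quantity.

### What the simulator does not emulate

Edges are conditionally independent given age — real connectomes have
rich spatial covariance, network community structure, and shared
physiological noise. There is no site/scanner effect, no motion
confounding, no hemispheric asymmetry beyond the planted focus effects,
and clinical covariates are generated independently of the connectomes.
Passing tests therefore demonstrate that the pipeline's mathematics and
bookkeeping are correct and that planted effects of known size are
recovered — not that the fingerprint separates outcomes in real patients.

One quantitative consequence of edge independence is worth stating: after
normative correction each edge has ~unit variance, so a lobe measure (a
2:1-weighted sum over 14 edges, averaged over ~9–12 ipsilateral lobe
nodes) has intrinsic between-subject noise of roughly 1.8 normative SD.
Planted measure shifts of 2–3 SD are therefore only ~1–1.7 noise units,
and end-to-end discrimination of the 7 unfavourable among 38 left-out
subjects plateaus around AUC 0.85–0.9 at the default effect size;
markedly higher AUC requires effects of ~4 SD or correlated deviations as
in real data.

## Numerical choices

* Input matrices must be symmetric within relative 1e-6; smaller
  asymmetries are averaged away, larger ones are errors. Missing values
  are errors naming the edge, never zeros.
* Correlations are clipped to $\pm(1 - 10^{-12})$ before Fisher-z, so
  degenerate series give large finite values, not infinities. Partial
  correlation residualizes both series on an intercept plus all confound
  columns jointly.
* The profile covariance is inverted by eigendecomposition with an
  eigenvalue floor of $10^{-10} \cdot \mathrm{trace}/6$: 40 profiles in 6
  dimensions are normally well-conditioned (the floor leaves the exact
  inverse untouched), but degenerate fingerprints — e.g. 40 identical
  profiles — contribute zero Mahalanobis distance instead of crashing.
* Matrix files are written with 17 significant digits so read/write
  round-trips are bit-exact; identical config + seed reproduces every
  output file bit-for-bit.
* Ranking ties (left-out subjects with equal total distance) receive
  average ranks.
* The 117-node fixture assumes the anterior/posterior hippocampal
  composites *replace* any whole-hippocampus node of the per-hemisphere
  parcellation, keeping the stated node total.

## Problem sizes used in the test suite

Unit tests run on 7–20-node-per-hemisphere atlases where brute-force
oracles are cheap; calibration and planted-signal checks use the
full-size cohort (117 nodes, 85 controls); replicate-heavy null
calibrations use 12-node-per-hemisphere cohorts with 25 controls and 100
permutation iterations; the scaled-down permutation check uses 500
iterations (the full analysis uses 5000). These sizes were chosen so the
whole suite exercises every full-scale path at least once while the
replicate loops stay small enough to iterate on.

## Known limitations

* The Euclidean + Mahalanobis sum mixes units; the package follows the
  method as defined and offers no rescaling.
* The fingerprint assumes a *unilateral* focus with a known side;
  bilateral or unknown-side patients have no defined orientation.
* The random-node null reuses one bootstrap expansion across iterations
  (by design, so the null varies only the node set); conclusions about
  expansion variability require varying the expansion seed explicitly.
* With 9 model subjects the fingerprint mean itself carries sampling
  noise that the distance scores inherit; the bootstrap expansion
  stabilizes the covariance but cannot add information.
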