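---
title: "Directional analysis of circumpapillary RNFL decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional analysis of circumpapillary RNFL decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circRNFL)
```

## The measurement and its coordinate system

Spectral-domain OCT samples retinal nerve fiber layer (RNFL) thickness at
`N` points (here 256) equally spaced along the 3.46 mm calculation circle
around the optic nerve head.  The points are indexed counterclockwise in
TSNIT order (Temporal, Superior, Nasal, Inferior, back to Temporal), so
point `j` sits at angle `(j - 1) * 360 / N` degrees — 1.41° apart at
`N = 256` — with the temporal point as the origin.  Healthy profiles show
the classic *double hump*: thick superior and inferior bundles, thin
temporal and nasal sectors.  Because the data live on a circle, summaries
such as "mean defect direction" need circular statistics, not linear ones.

## Angular Quantile and Angular Decay

Eyes are stratified into nine groups: age bands Age1 (40–49), Age2 (50–59),
Age3 (≥ 60) crossed with optic disc size Small (< 1.6 mm²), Average
(1.6–2.6 mm², bounds inclusive), Large (> 2.6 mm²).  For each group `G` and
each angular point `j`, the normative reference is the *empirical* CDF of
the normal eyes' thickness at that point,

$$\mathrm{eCDF}_{G,j}(x) = \frac{|\{r \le x : r \in R_{G,j}\}|}{|R_{G,j}|},$$

with no parametric smoothing across angles or covariates.  An eye's
**Angular Quantile** at `j` is this eCDF evaluated at its own thickness;
its **Angular Decay** is the complement `1 − quantile`.  Decay is a
pointwise rank: decay 0.9 at some direction means the eye is thinner there
than 90% of its normative group.  For a *normal* eye ranked against its own
group the transform is (discretely) probability-integral: decay is
approximately uniform on `[0, 1]` at every angular point, which the test
suite checks with Kolmogorov–Smirnov tests on generated cohorts.

Two conventions are deliberately pinned down where the counting definition
leaves room:

* the eCDF is right-continuous and counts ties with multiplicity;
* quantile inversion (for normative percentile contours) is *type 1* — the
  smallest order statistic reaching the target probability — so inverting
  the eCDF at a sample point returns that point exactly.  With interpolated
  quantiles the contours could differ by one order statistic in small
  groups; nothing downstream depends on the choice.

Normal eyes are ranked against a catalog that includes themselves; no
leave-one-out correction is applied.  At the group sizes the method is
meant for (hundreds of eyes) the self-contribution shifts a quantile by at
most `1/n`, far below the decay threshold resolution.  A warning is issued
for groups under 20 eyes.

## Petals and the directional indices

Fixing a quantile threshold `tau` (default 0.75, i.e. the last quartile of
normative decay), a **petal** is a maximal circular run of points whose
decay *strictly* exceeds `tau`; points equal to `tau` are outside.  Runs
are traced on the circle itself: the scan is rotated to start at a
sub-threshold point before run-length encoding, so a defect straddling the
temporal origin is one petal, and decay above threshold everywhere is a
single petal of width `N`.  From the petal set come:

* `nu` — the petal count;
* `pi*` — the widest petal; ties are broken by larger summed decay, then by
  smaller start index (deterministic and decay-respecting; the definition
  alone leaves ties unresolved);
* `mu*` — the decay-weighted circular mean of `pi*`'s member grid angles,
  `atan2(sum w sin θ, sum w cos θ)` with the raw decay values as weights
  `w` (not decay in excess of `tau`);
* `lambda* = width(pi*)/N` and `Lambda = (sum of petal widths)/N`, the local
  and global loss fractions, with `0 ≤ lambda* ≤ Lambda ≤ 1`.

When no point exceeds `tau`, `mu*`, `pi*` and `lambda*` are NA and
`nu = Lambda = 0`.  If the weighted resultant of `pi*` has length below
`1e-12` — possible only for a near-uniform full-circle petal — `mu*` is
reported NA with a warning rather than an arbitrary angle.

## von Mises mixture clustering

Collections of `mu*` directions are modelled as a finite mixture of von
Mises distributions `sum_k alpha_k vM(mu_k, kappa_k)` with density
`exp(kappa cos(x − mu)) / (2 pi I0(kappa))`.  Fitting is by EM:
responsibilities in the E-step; in the M-step the mixing proportions are
mean responsibilities, the locations are responsibility-weighted circular
means, and each concentration solves `A(kappa) = I1/I0(kappa) = R̄` at the
weighted mean resultant length.  Numerical choices:

* all computation in radians, all interfaces in degrees;
* `A⁻¹` by the Best–Fisher three-regime approximation refined with 5
  Newton steps (`A'(κ) = 1 − A/κ − A²`); `kappa` capped at 500, where the
  density is already essentially a point mass and Bessel scaling would
  otherwise overflow — identical repeated angles hit the cap by design;
* scaled Bessel functions (`besselI(..., expon.scaled = TRUE)`) throughout;
* 20 random-responsibility restarts, relative log-likelihood tolerance
  `1e-8`, at most 500 iterations.  Restarts use the standard short-run
  strategy: each gets a 75-iteration burn-in and only the best candidate by
  log-likelihood is polished to convergence, which preserves the "best of
  n restarts" semantics at a fraction of the cost;
* components are reported sorted by location in `[0, 360)` degrees, so fits
  are comparable across seeds (label switching resolved);
* the log-likelihood is accumulated with log-sum-exp and is non-decreasing
  across EM iterations, which the tests assert on every run.

The number of components is chosen by BIC, `−2ℓ + (3K − 1) log n` (K
locations, K concentrations, K − 1 free proportions).  Only the *argmin*
over K is treated as meaningful; published per-model BIC magnitudes from
other software are often scaled per observation and are not comparable
across implementations.  Eyes without a defined `mu*` are excluded from
fitting and reported as an excluded count by the CLI.

The package also provides the Jammalamadaka–SenGupta circular correlation
for paired direction samples (e.g. left/right eyes), with an explicit error
when either sample has no angular dispersion.

## Classification from the loss indices

Glaucomatous-versus-normal trees are CART-style: greedy binary splits
maximizing Gini impurity decrease over the loss-index features, thresholds
at midpoints between adjacent distinct values.  Two deliberate deviations
from off-the-shelf CART:

* every candidate split must pass a label-permutation test within its node
  (default 1000 permutations, significance 0.05) before acceptance, so each
  split carries a p-value and trees stay small (default depth cap 3,
  minimum splittable node 7) — the same reporting surface as
  conditional-inference trees, though the split statistic is Gini decrease
  rather than a conditional test, so published specificity values from such
  software are qualitative rather than exact references;
* leaves are labelled with *equal class priors*: a leaf predicts the class
  over-represented relative to the training prevalence, ties going to
  normal.  With a cohort that is 80–95% normal, raw majority voting
  degenerates to the useless all-normal classifier (specificity 1,
  sensitivity 0); prevalence correction is the standard CART remedy and
  makes specificity comparisons between models informative.

`fit_tree_by_cluster()` partitions eyes by their circular cluster label
first, fits an independent tree per cluster, and pools the predictions;
specificity (`TN/(TN+FP)`, normal negative) and the maximum leaf Gini are
reported for comparison with a single unpartitioned tree.

## The synthetic cohort generator

The generator exists so the whole pipeline is testable without clinical
data.  A normal eye is

```
mean_curve(theta) + group effect + eye offset + smooth angular noise
```

where `mean_curve` is a baseline plus two von Mises-shaped bumps
(superior/inferior humps; defaults 60 µm baseline, 55 and 62 µm amplitudes
at 80° and 280°, shape 2.5), group effects are additive (−3 µm per age
band, ±2 µm by disc class), the eye-level offset is normal with SD 7 µm,
and the angular noise (SD 5 µm) is white noise passed through a circular
moving average with half-width 5 points — the simplest wrap-consistent
correlated-noise model.  Thickness is floored at the 30 µm structural
measurement floor.  Ages are uniform over 40–79; disc areas log-normal
(meanlog `log 2.1`, sdlog 0.28), spanning all nine strata.

A glaucomatous eye is a normal draw multiplied by
`1 − depth · wedge(theta)`, the wedge being a von Mises bump whose `width`
parameter is its full width at half maximum — tapered like real focal loss
rather than a hard sector.  Each eye's defect centre is jittered around its
cluster's direction with SD 16°: clinically, defect directions scatter
around the arcuate bundles, and this SD corresponds to a von Mises
concentration near `1/(16°)² ≈ 13`, the range reported for tight clinical
decay clusters; with zero jitter the simulated `mu*` values collapse to
near point masses (concentrations in the hundreds) that no clinical cohort
shows, and mixture model selection then fragments each mode.  Cluster
membership and per-eye defect direction are recorded as ground truth.

What the generator does *not* emulate: axon-bundle trajectories, device
speckle and segmentation error, inter-eye correlation within a subject, and
age as a continuous effect.  Passing tests therefore demonstrate that the
*pipeline* recovers planted directional structure under realistic noise,
not that the method is validated on clinical data.

## Problem sizes and tolerances used by the checks

The test-suite and the acceptance script run, among others: mixture
recovery on 20 replicates of 300 directions drawn from a
diffuse-plus-tight two-cluster regime (locations 102° and 296°,
concentrations 11 and 1.56, proportions 0.304/0.696), requiring `K = 2`
and both locations within 10° in at least 18 of 20; and an end-to-end run
on 500 normal plus 100 glaucomatous synthetic eyes with defect clusters at
100° and 290° (depth 0.5, width 40°), requiring recovered modes within 10°
of truth, at least 90% cluster-assignment accuracy against the generator's
ground truth, and pooled specificity of cluster-partitioned trees no worse
than a global-loss-only tree.  Property checks use 10³ random circular
sequences against a brute-force petal oracle and 10⁴ draws for the index
ordering `0 ≤ lambda* ≤ Lambda ≤ 1`.

## Known limitations

* The normative catalog is strictly empirical; quantiles are as granular as
  the group sample, and small strata give coarse decay values.
* A single threshold `tau` per run; petal persistence across thresholds is
  out of scope.
* The mixture assumes von Mises components; heavy-tailed or skewed
  directional clusters will inflate `K`.
* Tree evaluation is in-sample, matching the reporting style of the
  analysis it mirrors; no cross-validation or ROC machinery is provided.
* The circular unimodality pretest sometimes used before mixture modelling
  is not implemented, since no specific test is mandated by the source
  analyses; BIC comparison against `K = 1` serves that role here.
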