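# circRNFL

Circular statistics for high-resolution circumpapillary RNFL profiles.

Spectral-domain OCT measures retinal nerve fiber layer (RNFL) thickness at
`N = 256` equally spaced angular points along the 3.46 mm calculation circle
around the optic nerve head, indexed counterclockwise in TSNIT order
(Temporal–Superior–Nasal–Inferior–Temporal, temporal origin at 0°, points
1.41° apart). Conventional analysis collapses this circle into 4 quadrants
or 12 clock-hours and discards the direction of focal loss. circRNFL keeps
both the granularity and the circularity: it is written for glaucoma
researchers and biostatisticians who want directionally precise structural
phenotyping of RNFL loss.

## What it computes

For eyes stratified into 9 groups (age bands 40–49 / 50–59 / ≥60 crossed
with optic disc size <1.6 / 1.6–2.6 / >2.6 mm²):

* **Normative catalog** — for every group `G` and angular point `j`, the
  empirical CDF of normal thickness,
  `eCDF_G,j(x) = |{r ≤ x : r ∈ R_G,j}| / |R_G,j|`
  (9 × 256 = 2304 direction-specific distributions when complete).
* **Angular Quantile / Angular Decay** — an eye's pointwise normative rank
  `eCDF_G,j(RNFL(i,j))` and its complement `1 − quantile`, both circular
  sequences in [0, 1]; high decay = locally thin relative to normals.
* **Petals** — maximal circular runs of decay strictly above a threshold
  `τ` (default 0.75), traced with wrap-around across the temporal origin.
  Per eye: petal count `ν`, widest petal `π*`, its decay-weighted circular
  mean direction `μ* = atan2(Σ w sinθ, Σ w cosθ)`, local loss
  `λ* = width(π*)/N` and global loss `Λ = Σ widths / N`, with
  `0 ≤ λ* ≤ Λ ≤ 1`.
* **von Mises mixture clustering** — EM fits of
  `Σ_k α_k vM(μ_k, κ_k)` to collections of `μ*` directions, `K` selected
  by BIC (`−2ℓ + (3K−1) log n`), plus the Jammalamadaka–SenGupta circular
  correlation.
* **Classification** — permutation-guarded Gini trees on `(Λ, λ*)`, fit
  globally or separately within each circular cluster, reporting
  specificity, sensitivity and leaf impurities.
* **Synthetic cohorts** — a seeded generator of normal (double-hump) and
  glaucomatous (focal wedge defect) profiles with ground truth, so every
  stage is testable without clinical data.

## Worked example

```r
library(circRNFL)
spec <- synthetic_spec()
set.seed(7)
normals  <- generate_normal(spec, 300)
glaucoma <- generate_glaucoma(spec,
  list(defect_spec(100, 40, 0.5), defect_spec(290, 40, 0.5)), n_eyes = 60)

catalog <- build_catalog(normals)
catalog
#> <normative_catalog> 9 group(s) x 256 angular points = 2304 eCDFs
#>   Age1:Average     43 eyes
#>   Age1:Large       20 eyes
#>   ...

decay   <- angular_decay(glaucoma, catalog)
summary <- summarize_decay(decay, tau = 0.75)
head(summary, 4)
#>   eye_id  tau nu theta_s theta_t   mu_star lambda_star    Lambda
#> 1  G0001 0.75  5      54      92 101.52589   0.1523438 0.1953125
#> 2  G0002 0.75  1      28      69  66.81407   0.1640625 0.1640625
#> 3  G0003 0.75 12     165     243 285.51146   0.3085938 0.8046875
#> 4  G0004 0.75  1     189     231 293.49785   0.1679688 0.1679688

fit <- select_K(summary$mu_star[!is.na(summary$mu_star)], 1:5, seed = 8)
fit
#> <vm_mixture> K = 2, n = 60, loglik = -45.412, BIC = 111.296
#>        mu  kappa alpha
#> 1  97.776 13.407   0.5
#> 2 286.652 18.060   0.5
```

Reading the output: eye `G0001` has five supra-threshold decay regions; its
widest spans points 54–92 (`λ*` ≈ 15% of the circle, all petals together
≈ 20%) and its decay-weighted direction `μ*` is 101.5° — superior. The
mixture model recovers the two planted defect clusters (100° and 290°)
with concentrations in the range seen in clinical decay clusters, and
`assign_clusters(fit, ...)` labels each eye.

`plot_decay()`, `plot_contours()` and `plot_rose()` draw the corresponding
polar figures (threshold circle at radius τ, sub-threshold decay in blue,
petals pink, widest petal red, dashed radial at `μ*`).

## Command line

A thin wrapper over the same functions
(`inst/cli/circrnfl.R`, or `rnfl_cli()` from R):

```sh
Rscript inst/cli/circrnfl.R simulate --seed 1 --n-normal 500 --n-glaucoma 100 --out work/
Rscript inst/cli/circrnfl.R build-catalog --data work/normal_data.csv \
    --metadata work/normal_metadata.csv --out work/catalog.csv
Rscript inst/cli/circrnfl.R decay --data work/glaucoma_data.csv \
    --metadata work/glaucoma_metadata.csv --catalog work/catalog.csv --out work/decay.csv
Rscript inst/cli/circrnfl.R petals --decay work/decay.csv --tau 0.75 --out work/petals.csv
Rscript inst/cli/circrnfl.R cluster --summary work/petals.csv --seed 2 \
    --model-out work/model.csv --cluster-out work/clusters.csv
```

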