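---
title: "Multi-trait GBLUP with NIR-predicted secondary phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait GBLUP with NIR-predicted secondary phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirblup)
```

## The problem

Wheat end-product quality traits — crumb yellowness (b\*), flour water
absorption, particle size index, flour yield, grain protein, flour swelling
volume — are assayed with destructive laboratory tests that need kilograms
of grain, so breeding programs measure them late and on few lines. Near
infrared (NIR) spectroscopy predictions of the same traits are cheap,
non-destructive, and available on tens of thousands of lines. Because the
NIR prediction of a trait is strongly genetically correlated with the
laboratory assay (published estimates run from 0.19 for flour swelling
volume to 0.86 for water absorption), the NIR values can serve as a
*correlated secondary trait* in a multi-trait genomic prediction model,
boosting the accuracy of genomic estimated breeding values (GEBVs) for the
expensive trait.

`nirblup` implements that analysis end to end: adjustment of unbalanced
multi-trial records to per-line BLUEs, a VanRaden genomic relationship
matrix (GRM), single-trait and bivariate GREML/GBLUP with per-trait
missingness, the cross-validation masking scenarios S0–S3 that govern which
NIR records accompany the training data, and year-wise forward prediction.
Because the motivating breeding dataset is proprietary, the package ships a
synthetic breeding-program generator with exact known truth, and every
stage is tested against it.

## Models

### Trial adjustment and heritability

Raw records are first screened per trait with a single-pass 4-SD edit, then
adjusted with the fixed-effects model

$$y = \mu + \mathrm{trial} + \mathrm{line} + e,$$

where *trial* is the concatenation of year, location and nursery — one
group factor, not three separate factors. Fitting *line* as fixed yields
BLUEs used as adjusted phenotypes; fitting it as random (REML, via lme4)
yields the line variance $\sigma^2_g$ and residual variance $\sigma^2_e$
that enter the line-mean broad-sense heritability

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e/(T R)},$$

with $T$ the mean number of trials per line and $R$ the mean number of
replicates per line-trial. With $T R = 1$ this is plot-level repeatability;
applied to the published variance components of the six wheat quality
traits it reproduces five of the six published $H^2$ values at two decimals
(grain protein computes to 0.39 against a published 0.40, consistent with a
per-trait $T R$ slightly above one — the source does not print $T$ or
$R$, so the package makes no guess).

The BLUE adjustment is performed once on the full dataset, *before* any
cross-validation masking: masking then hides adjusted values, not raw
records. This matches validating GEBVs against "corrected phenotypic
values" and keeps the masking semantics purely at the line level.

### GRM

The GRM is VanRaden's method 1 on observed-sample allele frequencies:
$W = M - 2p$ column-wise, missing dosages mean-imputed (zero after
centring), and

$$G = \frac{W W^\top}{2 \sum_j p_j (1 - p_j)}.$$

REML needs $G$ invertible, and a GRM built from fewer markers than lines is
rank-deficient, so `grm_condition()` adds a diagonal ridge (default
$10^{-6}$, raised if needed so the smallest eigenvalue reaches $10^{-8}$)
and records it. PCA of $G$ (scores = eigenvectors scaled by root
eigenvalues) is provided for population-structure inspection.

### GREML

The single-trait model is $y = 1\mu + Zu + e$ with
$u \sim N(0, G\sigma^2_g)$ and $e \sim N(0, I\sigma^2_e)$. The bivariate
model stacks the end-product and NIR BLUEs with per-trait intercepts,
genetic covariance $G_0 \otimes G$ (the 2×2 genetic covariance expanded
through the one GRM — the standard multi-trait GREML structure, and the
only one consistent with both traits' breeding values sharing one marker
relationship matrix), and unstructured residual covariance $R_0$ applied
within lines: a line observed for both traits contributes the full 2×2
residual block, a single-trait line only that trait's residual variance.
Records missing for a trait are **absent rows** of the likelihood, never
imputed — this is exactly what lets NIR-only lines inform the end-product
trait.

The restricted log-likelihood is evaluated with all constants,

$$\ell = -\tfrac12\left[\log|V| + \log|X^\top V^{-1}X| + y^\top P y
 + (n-p)\log 2\pi - \log|X^\top X|\right],$$

so it equals the log-density of orthonormal error contrasts; the test suite
verifies this against an independently coded dense-contrast oracle to
$10^{-10}$ on 100 random instances.

Optimization uses average-information (AI) updates on the variance
parameters. The fallback on a non-improving AI proposal is step-halving
toward the previous estimate combined with projection of $G_0$ and $R_0$
onto the positive-semidefinite cone (eigenvalue clipping at $10^{-8}$),
rather than an EM step: EM updates for the cross-trait covariance under
row-omission missingness have no clean closed form, and step-halving gives
the same monotone likelihood path and fixed point with less machinery.
Variances are floored at $10^{-8}$ times the trait's phenotypic variance;
starting values are half the phenotypic variance for variances, 0 for
covariances; convergence requires both the likelihood change and the
largest relative parameter change below `tol` (default $10^{-6}$, at most
100 iterations). BLUE standard errors are *not* carried into GREML as
weights; residuals are homoscedastic per trait.

GEBVs are BLUPs for **all** GRM lines, including unphenotyped ones,
$\hat u = \mathrm{Cov}(u, y)\, V^{-1}(y - X\hat b)$; the test suite checks
them against a dense conditional-mean oracle and against SNP-BLUP ridge
regression through the GBLUP/SNP-BLUP duality
($\lambda = c\,\sigma^2_e/\sigma^2_g$ with $c$ the VanRaden denominator).

Standard errors of variance parameters and of $\hat r_g$ (delta method) are
derived from the inverse AI matrix at the optimum and labelled as
observed-information SEs; the published correlation SEs' method is
unstated, so no equivalence is claimed. The reported phenotypic correlation
is, by default, the Pearson correlation of the two BLUE vectors over lines
observed for both traits; `r_p_method = "model"` switches to the
$G_0 + R_0$ derivation, since the published definition is ambiguous.

### Cross-validation scenarios and forward prediction

Folds partition the end-product-phenotyped *lines* (never records) into
five near-equal groups, repeated with fresh randomizations; all randomness
derives from one master seed through per-repeat substreams. The scenarios
are:

* **S0** — single-trait baseline, no NIR data;
* **S1** — bivariate, training restricted to non-validation lines observed
  for both traits;
* **S2** — S1 plus all NIR-only lines in the NIR training set;
* **S3** — S2 plus the validation lines' own NIR records (early NIR
  phenotyping of candidates).

The held-out end-product truth never enters any training structure; this is
asserted on every fold and a violation is a hard error. Accuracy is the raw
Pearson correlation between GEBVs and held-out BLUEs — no scaling by
$\sqrt{h^2}$. Folds whose REML fit fails are excluded from the mean and
counted, rather than imputed.

Forward prediction assigns each line to its first observation year — the
source does not state how lines spanning years were treated, so the
package picks the assignment that keeps a line's data out of validation
whenever any of it was available for training. For each test year the model
trains on all earlier-year lines (optionally with all their NIR data in a
bivariate model: whether the original analysis used all NIR data or
scenario-specific subsets is not fully specified, so both modes are
exposed) and predicts the new year's lines. Global BLUEs subset by year are
used, rather than re-adjusting within each training window.

## The synthetic generator

`sim_config()` + `simulate_genotypes()` + `simulate_phenotypes()` +
`apply_missingness()` emulate a breeding program:

* **Genotypes**: per-marker alternate-allele frequencies uniform on a
  configurable range, Hardy–Weinberg binomial dosages; optional half-sib
  family blocks (shared parental haplotype, contiguous with year cohorts)
  create relatedness turnover across breeding cycles.
* **Genetic architecture**: marker-effect pairs drawn bivariate normal and
  then linearly transformed so the *realized* genetic variances and
  correlation equal the targets exactly, at any sample size. Phenotypes are
  on a unit-variance scale per trait ($\sigma^2_g = h^2$,
  $\sigma^2_e = 1 - h^2$), so generating parameters are directly comparable
  to REML estimates. This exactness is what permits tight
  parameter-recovery tests.
* **Trial structure**: each line belongs to one cohort year, a configurable
  fraction carries over to the next year, lines spread round-robin over
  trials with one bridging line between neighbouring trials — the
  line-by-trial graph is connected, so trial effects (i.i.d. normal per
  trial and trait, default SD 1 in trait units) are estimable. One record
  per line-trial reflects composite-sample quality assays.
* **NIR as a trait**: NIR instrument error is folded into the NIR trait's
  residual; no spectra are simulated. All six quality traits would be
  treated symmetrically — the generator knows only "EP" and "NIR".
* **Unbalance**: `apply_missingness()` retains configured numbers of lines
  per year and trait, preferring to keep NIR on the lines that also have
  the end-product assay (the overlap scenario S1 needs). Both directions of
  imbalance (more EP than NIR in a year, and the reverse) are
  representable, as the published per-year counts require.

What the generator does **not** emulate: linkage disequilibrium and
recombination maps, selection and multi-generation breeding,
genotype-by-environment interaction, spatial field trends, and NIR
calibration drift. Passing tests therefore demonstrate correctness of the
estimation machinery and the masking logic under a clean additive world,
not robustness to those real-data phenomena.

## Numerical and design choices

* Default genetic parameters follow the published crumb-yellowness
  estimates (SNP $h^2$ 0.68, $r_g$ 0.83); the residual correlation defaults
  to 0.30, chosen so the implied phenotypic correlation of paired records
  is near the published 0.46.
* Allele frequencies for centring come from the observed sample; no
  base-population frequencies are assumed.
* `min_maf` defaults to 0 (no marker filtering), matching the source's
  silence on MAF editing.
* The outlier edit uses global per-trait moments (not per-trial): the
  source does not stratify, and a single pass is specified. A consequence,
  exercised in the tests, is that in tiny samples one extreme value can
  inflate the SD enough to survive.
* BLUE corner-point constraints use the first trial and line as reference;
  the reported BLUE is intercept + line effect, so single-trial designs
  return raw values and line differences are invariant to the reference
  choice. A line confounded with its own singleton trial gets its raw mean
  with an infinite SE rather than silently distorting other effects.
* With independent traits ($r_g = r_e = 0$) the bivariate fit is only
  *asymptotically* separable: finite-sample REML estimates of the
  cross-trait covariances are $O(n^{-1/2})$ and couple the traits. The
  suite tests exact reduction when the second trait's records are deleted,
  and near-separability (within 0.05 on variances at 250 lines, within
  0.02 on forward accuracies at 400 lines).

## Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to make each property sharp yet
keep the whole suite quick on a laptop core: parameter recovery at 400
lines × 1000 markers over 10 seeds (estimates of $h^2$ within ±0.10 and
$r_g$ within ±0.15 of truth); the scenario-ordering experiment at 200
end-product lines with 5× NIR-only lines, 500 markers, fivefold × 3
repeats (S2 and S3 beat S0 by a paired one-sided test at $\alpha = 0.05$;
S1 is not significantly below S0); the forward-prediction trend at 300
lines over five cohort years and 10 seeds; and the null-accuracy check
averaged over three independent 300-line datasets, because a single
dataset's mean CV accuracy under $h^2 = 0$ carries dataset-level noise of a
few hundredths.

## Known limitations

* Two traits only; no multi-environment or GxE covariance structures, no
  Bayesian whole-genome regressions — deliberate non-goals.
* Dense-matrix REML: fine up to a few thousand records per fit; the
  published 27K-line NIR dataset would need sparse or rotation tricks the
  package does not implement.
* The trial-connectivity requirement in `fit_blues()` is strict; designs
  thinned so hard that trials disconnect must be re-thinned or fitted per
  component.
* Heritability from GREML refers to the BLUE (line-mean) scale; no
  back-transformation to plot level is attempted.

## A worked run

```{r, eval = FALSE}
cfg <- list(
  simulation = list(n_lines = 200, n_markers = 500, years = 2012:2015,
                    h2_ep = 0.68, h2_nir = 0.68, r_g = 0.83),
  seed = 1,
  cv = list(k = 5, repeats = 2, scenarios = c("S0", "S1", "S2", "S3")),
  forward = list(test_years = c("2014", "2015"), mode = "multi")
)
manifest <- run_pipeline(cfg, "demo_run")
```

The manifest lists every output (BLUEs, GRM and its PCA, variance
components, GEBVs, per-fold and per-year accuracies) and echoes the full
configuration, so the run can be reproduced from the manifest alone.
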