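# nirblup

Multi-trait genomic prediction of wheat end-product quality traits using
NIR-predicted secondary phenotypes.

## Who this is for

End-product quality traits of bread wheat — crumb yellowness (b\*), water
absorption, particle size index, flour yield, grain protein, flour swelling
volume — are assayed with destructive laboratory tests that require
kilograms of flour, so breeding programs can afford them only late and on
few lines. Near-infrared (NIR) predictions of the same traits are cheap and
available on vastly more lines, and they are genetically correlated with
the laboratory assays. `nirblup` is for quantitative geneticists and
breeding analysts who want to exploit that correlation: it treats the NIR
prediction as a second trait in a bivariate GBLUP model so that NIR-only
lines enlarge the training set for the expensive trait.

## The model

Phenotypes are adjusted to per-line BLUEs with the fixed-effects model
`value = mean + trial + line + error` (trial = year x location x nursery as
one group factor), after a single-pass 4-SD outlier edit. Line-mean
broad-sense heritability is

    H2 = s2_g / (s2_g + s2_e / (T * R))

with T the mean trials per line and R the mean replications per line-trial.

Genomic prediction is GBLUP with a VanRaden genomic relationship matrix
`G = WW' / (2 * sum p_j (1 - p_j))` built from centred SNP dosages.
Variance components come from REML: single-trait
`y = 1u + Zu + e, u ~ N(0, G s2_g)`, or bivariate with genetic covariance
`G0 (x) G` and unstructured residual covariance `R0` applied within lines,
with per-trait missing records simply omitted from the likelihood (never
imputed). The optimizer is average-information REML with step-halving and
positive-semidefinite projection.

Prediction accuracy is the Pearson correlation between GEBVs and held-out
BLUEs, estimated by fivefold cross-validation under four masking scenarios
— S0: single-trait baseline; S1: paired end-product + NIR training; S2:
plus all NIR-only lines; S3: plus the validation candidates' own NIR
records — and by year-wise forward prediction (train on earlier breeding
cycles, predict the next year's new lines).

Because real programs' datasets are proprietary, the package includes a
synthetic breeding-program generator whose realized genetic variances and
correlation hit their targets exactly, so every stage is testable with
known truth.

## Worked example

Simulate a breeding program (400 lines, 1000 SNPs, heritabilities 0.6/0.7,
genetic correlation 0.8 between the lab assay "EP" and its NIR prediction),
then estimate the genetic architecture:

```r
library(nirblup)

cfg  <- sim_config(n_lines = 400, n_markers = 1000, years = "2012",
                   n_trials_per_year = 2, h2_ep = 0.6, h2_nir = 0.7,
                   r_g = 0.8, seed = 1)
geno <- simulate_genotypes(cfg)
sim  <- simulate_phenotypes(geno, cfg)
grm  <- grm_condition(build_grm(geno))
grm
#> Genomic relationship matrix: 400 lines, 1000 markers, ridge 1e-06
#>   mean diagonal 0.995

blues_ep  <- fit_blues(sim$phenotypes, "EP")
blues_nir <- fit_blues(sim$phenotypes, "NIR")
fit_bivariate(blues_ep, blues_nir, grm)
#> Bivariate GREML fit (9 iterations, converged)
#>   genetic correlation r_g = 0.848 (SE 0.084), phenotypic r_p = 0.600
#>   h2: EP = 0.406, NIR = 0.854; restricted loglik = -1050.6332
```

The REML estimates recover the generating parameters within their sampling
error (with 1000 markers the SE of an h2 estimate is about 0.1; averages
over 10 seeds land within 0.10 of 0.6/0.7 and within 0.15 of r_g = 0.8 —
that check runs in the test suite).

Now the question the package exists for: does adding NIR records help
predict the expensive trait? Thin the design to 200 lab-assayed lines among
1200 NIR-recorded lines and compare the masking scenarios:

```r
cfg  <- sim_config(n_lines = 1200, n_markers = 500, years = "2012",
                   n_trials_per_year = 1, h2_ep = 0.6, h2_nir = 0.7,
                   r_g = 0.8, lines_per_year_ep = 200,
                   lines_per_year_nir = 1200, seed = 2)
geno <- simulate_genotypes(cfg)
ph   <- apply_missingness(simulate_phenotypes(geno, cfg)$phenotypes, cfg)
grm  <- grm_condition(build_grm(geno))
blues_ep  <- fit_blues(ph, "EP")
blues_nir <- fit_blues(ph, "NIR")

plan <- make_folds(blues_ep$line_id, k = 5, repeats = 1, seed = 2)
run_cv(blues_ep, blues_nir, grm, plan)
#> Prediction accuracy report (cv)
#>  scenario  mean     sd n_folds n_failed
#>        S0 0.355 0.0958       5        0
#>        S1 0.410 0.0710       5        0
#>        S2 0.559 0.0653       5        0
#>        S3 0.641 0.0631       5        0
```

Accuracy climbs from 0.36 (single trait) to 0.64 as paired NIR records
(S1), NIR-only lines (S2), and finally the candidates' own NIR records (S3)
enter training — the qualitative pattern that motivates NIR-assisted
selection. `run_forward()` produces the analogous per-year forward
prediction report, and `run_pipeline()` drives the whole chain from a
single configuration with a reproducibility manifest.

Worked arithmetic on published wheat estimates is also built in: with the
published variance components for crumb yellowness (s2_g = 0.86,
s2_e = 0.13) and T*R = 1,

```r
broad_h2(0.86, 0.13)
#> [1] 0.8686869
```

which rounds to the published H2 of 0.87.

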