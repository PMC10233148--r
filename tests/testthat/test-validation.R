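toy_blues <- function(ids, seed = 1) {
  set.seed(seed)
  data.frame(line_id = ids, blue = rnorm(length(ids)))
}

test_that("fold construction partitions lines evenly and reproducibly", {
  plan <- make_folds(sprintf("L%02d", 1:10), k = 5, repeats = 3, seed = 4)
  for (r in 1:3) {
    expect_equal(unname(table(plan$folds[[r]])), rep(2L, 5),
                 ignore_attr = TRUE)
    expect_setequal(names(plan$folds[[r]]), sprintf("L%02d", 1:10))
  }
  # uneven division: sizes differ by at most one
  plan2 <- make_folds(sprintf("L%02d", 1:13), k = 5, repeats = 1, seed = 4)
  sizes <- table(plan2$folds[[1]])
  expect_lte(max(sizes) - min(sizes), 1)

  expect_identical(make_folds(sprintf("L%02d", 1:10), 5, 3, seed = 4),
                   plan)
  expect_false(identical(plan$folds[[1]], plan$folds[[2]]))
  expect_error(make_folds(c("A", "B"), k = 5), class = "nirblup_config_error")
})

test_that("scenario masking follows the S0-S3 information ordering", {
  both <- sprintf("B%d", 1:6)
  nir_only <- sprintf("N%d", 1:4)
  blues_ep <- toy_blues(both, 1)
  blues_nir <- toy_blues(c(both, nir_only), 2)
  plan <- make_folds(both, k = 3, repeats = 1, seed = 9)
  fold <- 1
  val <- names(plan$folds[[1]])[plan$folds[[1]] == fold]

  s0 <- apply_scenario(plan, fold, 1, blues_ep, blues_nir, "S0")
  s1 <- apply_scenario(plan, fold, 1, blues_ep, blues_nir, "S1")
  s2 <- apply_scenario(plan, fold, 1, blues_ep, blues_nir, "S2")
  s3 <- apply_scenario(plan, fold, 1, blues_ep, blues_nir, "S3")

  # every end-product line also has NIR here, so S0 and S1 train on the
  # same end-product records; S0 uses no NIR at all
  expect_setequal(s0$train_ep$line_id, s1$train_ep$line_id)
  expect_equal(nrow(s0$train_nir), 0)
  # S2 adds exactly the NIR-only lines; S3 additionally the candidates' NIR
  expect_setequal(s2$train_nir$line_id,
                  c(s1$train_nir$line_id, nir_only))
  expect_setequal(setdiff(s3$train_nir$line_id, s2$train_nir$line_id), val)
  # nesting of training record sets
  expect_true(all(s1$train_nir$line_id %in% s2$train_nir$line_id))
  expect_true(all(s2$train_nir$line_id %in% s3$train_nir$line_id))
  # the held-out truth never appears in training, under any scenario
  for (s in list(s0, s1, s2, s3)) {
    expect_length(intersect(s$truth_ep$line_id, s$train_ep$line_id), 0)
    expect_setequal(s$truth_ep$line_id, val)
  }
  # counts from a worked micro-example: val fold of 2 -> S2 trains NIR on
  # 4 paired + 4 NIR-only = 8 lines, S3 on all 10
  expect_equal(nrow(s2$train_nir), 4 + 4)
  expect_equal(nrow(s3$train_nir), 10)
})

test_that("no masked end-product value leaks into training in any fold", {
  s <- sim_one_year(n_lines = 120, n_markers = 60, seed = 21,
                    lines_per_year_ep = 50, lines_per_year_nir = 110)
  plan <- make_folds(s$blues_ep$line_id, k = 5, repeats = 2, seed = 5)
  for (r in 1:2) {
    for (f in 1:5) {
      for (sc in c("S0", "S1", "S2", "S3")) {
        sets <- apply_scenario(plan, f, r, s$blues_ep, s$blues_nir, sc)
        expect_length(intersect(sets$truth_ep$line_id,
                                sets$train_ep$line_id), 0)
        if (sc != "S3" && !is.null(sets$train_nir)) {
          expect_length(intersect(sets$truth_ep$line_id,
                                  sets$train_nir$line_id), 0)
        }
      }
    }
  }
})

test_that("cross-validation reports are deterministic and well formed", {
  s <- sim_one_year(n_lines = 90, n_markers = 150, seed = 22,
                    lines_per_year_ep = 45, lines_per_year_nir = 90)
  plan <- make_folds(s$blues_ep$line_id, k = 5, repeats = 1, seed = 7)
  rep1 <- run_cv(s$blues_ep, s$blues_nir, s$grm, plan,
                 scenarios = c("S0", "S3"))
  rep2 <- run_cv(s$blues_ep, s$blues_nir, s$grm, plan,
                 scenarios = c("S0", "S3"))
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1$folds), 10)
  expect_true(all(abs(rep1$folds$r[rep1$folds$converged]) <= 1))
  expect_setequal(rep1$summary$scenario, c("S0", "S3"))
})

test_that("null heritability gives null cross-validated accuracy", {
  # a single dataset carries dataset-level noise of a few hundredths, so
  # the null is averaged over independent simulated datasets
  means <- sapply(1:3, function(sd) {
    s <- sim_one_year(n_lines = 300, n_markers = 300, h2_ep = 0, seed = sd)
    plan <- make_folds(s$blues_ep$line_id, k = 5, repeats = 2, seed = sd)
    run_cv(s$blues_ep, NULL, s$grm, plan, scenarios = "S0")$summary$mean
  })
  expect_lt(abs(mean(means)), 0.1)
})

test_that("random permutation of GEBVs is a negative control", {
  s <- sim_one_year(n_lines = 100, n_markers = 200, seed = 24)
  fit <- fit_single_trait(s$blues_ep, s$grm)
  truth <- s$blues_ep$blue
  gebv <- unname(predict_gebv(fit, s$blues_ep$line_id))
  set.seed(9)
  perm_r <- replicate(300, cor(sample(gebv), truth))
  expect_lt(abs(mean(perm_r)), 0.05)
  expect_gt(cor(gebv, truth), mean(perm_r) + 3 * sd(perm_r))
})

test_that("forward splits honour first-observation years", {
  ph <- data.frame(
    line_id = c("A", "A", "B", "C", "D", "E"),
    year = c("2014", "2016", "2014", "2015", "2016", "2016"),
    location = "VIC", nursery = "N1", trait = "EP", value = 1:6
  )
  ly <- line_first_year(ph)
  expect_equal(ly$first_year[ly$line_id == "A"], "2014")
  blues_ep <- toy_blues(c("A", "B", "C", "D", "E"), 3)
  sp <- forward_split(blues_ep, NULL, ly,
                      train_years = c("2014", "2015"), test_year = "2016")
  # A appears in 2014 and 2016: training member, not validation
  expect_true("A" %in% sp$train_ep$line_id)
  expect_setequal(sp$val_lines, c("D", "E"))
  expect_length(intersect(sp$train_ep$line_id, sp$truth_ep$line_id), 0)
  expect_error(forward_split(blues_ep, NULL, ly,
                             train_years = "2014", test_year = "2015",
                             mode = "single"),
               NA)
  expect_error(forward_split(blues_ep, NULL, ly,
                             train_years = c("2014", "2015"),
                             test_year = "2017"),
               class = "nirblup_data_error")
  expect_error(forward_split(blues_ep, NULL, ly,
                             train_years = c("2014", "2016"),
                             test_year = "2016"),
               class = "nirblup_config_error")
})

test_that("forward prediction aggregates per-year accuracies", {
  cfg <- sim_config(n_lines = 200, n_markers = 250, years = 2012:2015,
                    h2_ep = 0.6, h2_nir = 0.7, r_g = 0.8, seed = 25)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  grm <- grm_condition(build_grm(geno))
  b_ep <- fit_blues(sim$phenotypes, "EP")
  b_nir <- fit_blues(sim$phenotypes, "NIR")
  ly <- line_first_year(sim$phenotypes)
  rep <- run_forward(b_ep, b_nir, grm, ly, test_years = c("2014", "2015"),
                     mode = "multi")
  expect_equal(nrow(rep$folds), 2)
  expect_true(all(abs(rep$folds$r) <= 1))
  expect_equal(rep$summary$mean, mean(rep$folds$r))

  # with independent traits, multi-trait forward prediction reduces to
  # single-trait accuracy
  # the cross-trait variance estimates shrink as 1/sqrt(n); at 400 lines
  # the residual coupling is below the stated 0.02
  cfg0 <- sim_config(n_lines = 400, n_markers = 300, years = 2012:2015,
                     h2_ep = 0.6, h2_nir = 0.7, r_g = 0, r_e = 0, seed = 26)
  geno0 <- simulate_genotypes(cfg0)
  sim0 <- simulate_phenotypes(geno0, cfg0)
  grm0 <- grm_condition(build_grm(geno0))
  b_ep0 <- fit_blues(sim0$phenotypes, "EP")
  b_nir0 <- fit_blues(sim0$phenotypes, "NIR")
  ly0 <- line_first_year(sim0$phenotypes)
  r_multi <- run_forward(b_ep0, b_nir0, grm0, ly0,
                         test_years = c("2014", "2015"), mode = "multi")
  r_single <- run_forward(b_ep0, NULL, grm0, ly0,
                          test_years = c("2014", "2015"), mode = "single")
  expect_lt(max(abs(r_multi$folds$r - r_single$folds$r)), 0.02)
})

test_that("cross-validation outpaces forward prediction under family turnover", {
  # families aligned with year cohorts: future-year lines are less related
  # to the training set, which deflates forward accuracy relative to CV
  cfg <- sim_config(n_lines = 240, n_markers = 300, years = 2012:2015,
                    h2_ep = 0.6, h2_nir = 0.7, r_g = 0.8,
                    n_families = 40, carryover_frac = 0.1, seed = 27)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  grm <- grm_condition(build_grm(geno))
  b_ep <- fit_blues(sim$phenotypes, "EP")
  b_nir <- fit_blues(sim$phenotypes, "NIR")
  ly <- line_first_year(sim$phenotypes)
  plan <- make_folds(b_ep$line_id, k = 5, repeats = 2, seed = 10)
  cv <- run_cv(b_ep, b_nir, grm, plan, scenarios = "S3")
  fw <- run_forward(b_ep, b_nir, grm, ly, test_years = c("2014", "2015"),
                    mode = "multi")
  expect_gt(cv$summary$mean, fw$summary$mean)
})
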