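test_that("restricted likelihood matches an independent dense oracle", {
  errs1 <- sapply(1:15, function(s) check_against_oracle(random_instance(s, 1)))
  errs2 <- sapply(1:15, function(s) check_against_oracle(random_instance(1000 + s, 2)))
  expect_lt(max(errs1, errs2), 1e-10)
})

test_that("likelihood has the closed-form scale equivariance", {
  inst <- random_instance(5, 2)
  ll <- reml_loglik(inst$blues[[1]], inst$blues[[2]], inst$grm,
                    inst$G0, inst$R0)
  cc <- 3.7
  b1 <- inst$blues[[1]]; b1$blue <- b1$blue * cc
  b2 <- inst$blues[[2]]; b2$blue <- b2$blue * cc
  ll_sc <- reml_loglik(b1, b2, inst$grm, cc^2 * inst$G0, cc^2 * inst$R0)
  n <- nrow(inst$blues[[1]]) + nrow(inst$blues[[2]])
  expect_equal(ll_sc, ll - (n - 2) * log(cc), tolerance = 1e-8)
})

test_that("with an identity GRM only the total variance is identified", {
  ids <- sprintf("L%02d", 1:12)
  grm <- structure(list(values = diag(12), line_ids = ids, n_markers = NA,
                        ridge_applied = 0), class = "nb_grm")
  dimnames(grm$values) <- list(ids, ids)
  set.seed(2)
  blues <- data.frame(line_id = ids, blue = rnorm(12))
  ll_a <- reml_loglik(blues, NULL, grm, G0 = 0.3, R0 = 0.7)
  ll_b <- reml_loglik(blues, NULL, grm, G0 = 0.9, R0 = 0.1)
  expect_equal(ll_a, ll_b, tolerance = 1e-10)
})

test_that("indefinite parameter sets are rejected with context", {
  inst <- random_instance(3, 1)
  expect_error(reml_loglik(inst$blues[[1]], NULL, inst$grm,
                           G0 = -2, R0 = 1e-12),
               class = "nirblup_compute_error")
})

test_that("the fitted single-trait model is a stationary point", {
  s <- sim_one_year(n_lines = 120, n_markers = 250, h2_ep = 0.5, seed = 10)
  fit <- fit_single_trait(s$blues_ep, s$grm)
  expect_true(fit$converged)
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
  ll0 <- reml_loglik(s$blues_ep, NULL, s$grm, fit$sigma2_g, fit$sigma2_e)
  expect_equal(ll0, fit$loglik, tolerance = 1e-8)
  for (dg in c(0.95, 1.05)) {
    for (de in c(0.95, 1.05)) {
      if (dg == 1 && de == 1) next
      ll <- reml_loglik(s$blues_ep, NULL, s$grm,
                        fit$sigma2_g * dg, fit$sigma2_e * de)
      expect_lte(ll, ll0 + 1e-6)
    }
  }
})

test_that("single-trait fit is invariant to line order", {
  s <- sim_one_year(n_lines = 60, n_markers = 120, seed = 12)
  fit <- fit_single_trait(s$blues_ep, s$grm)
  set.seed(1)
  perm <- sample(nrow(s$blues_ep))
  fit_p <- fit_single_trait(s$blues_ep[perm, ], s$grm)
  expect_equal(fit_p$sigma2_g, fit$sigma2_g, tolerance = 1e-8)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(fit_p$gebv, fit$gebv, tolerance = 1e-8)
})

test_that("GEBVs match a dense conditional-mean oracle on held-out lines", {
  # single trait: 15 lines, 5 unphenotyped
  s <- sim_one_year(n_lines = 15, n_markers = 40, seed = 13)
  obs <- s$blues_ep[1:10, ]
  fit <- fit_single_trait(obs, s$grm)
  G <- s$grm$values
  li <- match(obs$line_id, s$grm$line_ids)
  V <- fit$sigma2_g * G[li, li] + diag(fit$sigma2_e, 10)
  X <- matrix(1, 10)
  b <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, obs$blue))
  u_or <- fit$sigma2_g * G[, li] %*% solve(V, obs$blue - drop(X %*% b))
  expect_equal(unname(fit$gebv), unname(drop(u_or)), tolerance = 1e-8)

  held <- setdiff(s$grm$line_ids, obs$line_id)
  expect_equal(unname(predict_gebv(fit, held)),
               unname(drop(u_or))[match(held, s$grm$line_ids)], tolerance = 1e-8)

  # bivariate: oracle on the Kronecker-structured covariance
  s2 <- sim_one_year(n_lines = 15, n_markers = 40, seed = 14)
  ep <- s2$blues_ep[1:11, ]; nir <- s2$blues_nir[3:15, ]
  fitb <- fit_bivariate(ep, nir, s2$grm)
  ids <- s2$grm$line_ids
  trait <- c(rep(1, nrow(ep)), rep(2, nrow(nir)))
  lidx <- c(match(ep$line_id, ids), match(nir$line_id, ids))
  y <- c(ep$blue, nir$blue)
  Vb <- oracle_assemble_V(trait, lidx, s2$grm$values, fitb$G0, fitb$R0)
  Xb <- cbind(as.numeric(trait == 1), as.numeric(trait == 2))
  bb <- solve(t(Xb) %*% solve(Vb, Xb), t(Xb) %*% solve(Vb, y))
  r <- y - drop(Xb %*% bb)
  Cov_ep <- cbind(fitb$G0[1, 1] * s2$grm$values[, lidx[trait == 1]],
                  fitb$G0[1, 2] * s2$grm$values[, lidx[trait == 2]])
  u_ep_or <- Cov_ep %*% solve(Vb, r)
  expect_equal(unname(fitb$gebv_ep), unname(drop(u_ep_or)), tolerance = 1e-8)
})

test_that("duplicated lines and vanishing genetic variance behave as limits", {
  # duplicate GRM row/column: identical GEBVs
  cfg <- sim_config(n_lines = 20, n_markers = 60, years = "2012",
                    n_trials_per_year = 1, seed = 15)
  X <- simulate_genotypes(cfg)
  X <- rbind(X, dup = X[1, ])
  rownames(X)[21] <- "L_dup"
  grm <- grm_condition(build_grm(X))
  s <- simulate_phenotypes(X[1:20, , drop = FALSE],
                           sim_config(n_lines = 20, n_markers = 60,
                                      years = "2012", n_trials_per_year = 1,
                                      seed = 15))
  blues <- fit_blues(s$phenotypes, "EP")
  fit <- fit_single_trait(blues, grm)
  expect_equal(unname(fit$gebv["L_dup"]), unname(fit$gebv["L0001"]),
               tolerance = 1e-6)

  # pure-noise trait: variance pinned near the floor, GEBVs collapse to 0
  s0 <- sim_one_year(n_lines = 80, n_markers = 150, h2_ep = 0, seed = 16)
  fit0 <- fit_single_trait(s0$blues_ep, s0$grm)
  expect_lt(fit0$h2, 0.15)
  expect_lt(max(abs(fit0$gebv)), 0.35 * sd(s0$blues_ep$blue))

  expect_error(predict_gebv(fit0, "NO_SUCH_LINE"),
               class = "nirblup_data_error")
})

test_that("bivariate fit nests its constrained versions", {
  s <- sim_one_year(n_lines = 80, n_markers = 150, seed = 17)
  fit <- fit_bivariate(s$blues_ep, s$blues_nir, s$grm)
  expect_true(fit$converged)
  expect_lte(abs(fit$r_g), 1)
  expect_equal(fit$r_g, fit$G0[1, 2] / sqrt(fit$G0[1, 1] * fit$G0[2, 2]))

  # constrained fit with the genetic covariance pinned at zero
  inst <- nirblup:::greml_instance(list(s$blues_ep, s$blues_nir), s$grm)
  con <- nirblup:::ai_reml(inst, free = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_gte(fit$loglik, con$loglik - 1e-6)
})

test_that("deleting the second trait reduces the bivariate fit to single-trait", {
  s <- sim_one_year(n_lines = 60, n_markers = 120, seed = 18)
  fit1 <- fit_single_trait(s$blues_ep, s$grm)
  expect_warning(
    fitb <- fit_bivariate(s$blues_ep, s$blues_nir[0, ], s$grm),
    "fewer than 2"
  )
  expect_equal(fitb$G0[1, 1], fit1$sigma2_g, tolerance = 1e-4)
  expect_equal(fitb$R0[1, 1], fit1$sigma2_e, tolerance = 1e-4)
  expect_equal(unname(fitb$gebv_ep), unname(fit1$gebv), tolerance = 1e-4)
})

test_that("independent traits give a near-separable bivariate fit", {
  s <- sim_one_year(n_lines = 250, n_markers = 400, h2_ep = 0.5,
                    h2_nir = 0.5, r_g = 0, r_e = 0, seed = 19)
  fit1 <- fit_single_trait(s$blues_ep, s$grm)
  fitb <- fit_bivariate(s$blues_ep, s$blues_nir, s$grm)
  # realized genetic correlation is exactly 0; the REML estimate of the
  # cross-trait parameters is small, and the EP-trait components agree
  # with the single-trait fit to within finite-sample coupling
  expect_lt(abs(fitb$r_g), 0.25)
  expect_equal(fitb$G0[1, 1], fit1$sigma2_g, tolerance = 0.05)
  expect_equal(fitb$R0[1, 1], fit1$sigma2_e, tolerance = 0.05)
  m <- match(s$truth$true_bv$line_id, names(fitb$gebv_ep))
  expect_gt(cor(fitb$gebv_ep[m], s$truth$true_bv$bv_ep), 0.5)
})
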