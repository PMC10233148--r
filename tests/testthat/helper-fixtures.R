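# Shared fixtures, all generated in code.

# Small conditioned GRM from random dosages.
toy_grm <- function(n_lines = 20, n_markers = 50, seed = 42) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers,
                    years = "2012", seed = seed)
  grm_condition(build_grm(simulate_genotypes(cfg)))
}

# One-year, one-trial simulation: BLUEs are raw values minus a common trial
# effect, so GREML sees one record per line per trait.
sim_one_year <- function(n_lines, n_markers, h2_ep = 0.6, h2_nir = 0.7,
                         r_g = 0.8, r_e = 0.3, seed = 1, ...) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers,
                    years = "2012", n_trials_per_year = 1,
                    h2_ep = h2_ep, h2_nir = h2_nir, r_g = r_g, r_e = r_e,
                    seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  pheno <- apply_missingness(sim$phenotypes, cfg)
  grm <- grm_condition(build_grm(geno))
  list(config = cfg, geno = geno, pheno = pheno, truth = sim$truth,
       grm = grm,
       blues_ep = fit_blues(pheno, "EP"),
       blues_nir = fit_blues(pheno, "NIR"))
}

# Independent restricted-likelihood oracle: the log-density of orthonormal
# error contrasts K'y ~ N(0, K'VK), assembled with plain dense algebra.
# Shares no code with the package's chol-based evaluation.
oracle_reml_loglik <- function(y, X, V) {
  n <- length(y)
  p <- qr(X)$rank
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  S <- t(K) %*% V %*% K
  z <- drop(t(K) %*% y)
  -0.5 * (determinant(S, logarithm = TRUE)$modulus[1] +
            drop(t(z) %*% solve(S, z)) +
            (n - p) * log(2 * pi))
}

# Assemble the dense phenotypic covariance of stacked records by brute force.
oracle_assemble_V <- function(trait, lidx, G, G0, R0) {
  n <- length(trait)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      V[i, j] <- G0[trait[i], trait[j]] * G[lidx[i], lidx[j]] +
        if (lidx[i] == lidx[j]) R0[trait[i], trait[j]] else 0
    }
  }
  V
}

random_instance <- function(seed, n_traits = 1) {
  set.seed(seed)
  n_lines <- sample(4:20, 1)
  W <- matrix(rnorm(n_lines * (n_lines + 10)), n_lines)
  G <- tcrossprod(W) / (n_lines + 10)
  ids <- sprintf("L%02d", seq_len(n_lines))
  dimnames(G) <- list(ids, ids)
  grm <- structure(list(values = G, line_ids = ids, n_markers = NA,
                        ridge_applied = 0), class = "nb_grm")
  if (n_traits == 1) {
    obs <- sort(sample(n_lines, max(3, n_lines - sample(0:3, 1))))
    blues <- data.frame(line_id = ids[obs], blue = rnorm(length(obs)))
    G0 <- matrix(runif(1, 0.2, 2), 1, 1)
    R0 <- matrix(runif(1, 0.2, 2), 1, 1)
    list(grm = grm, blues = list(blues), G0 = G0, R0 = R0)
  } else {
    obs1 <- sort(sample(n_lines, max(3, n_lines - sample(0:3, 1))))
    obs2 <- sort(sample(n_lines, max(3, n_lines - sample(0:3, 1))))
    A <- matrix(rnorm(4), 2); G0 <- crossprod(A) + diag(0.1, 2)
    B <- matrix(rnorm(4), 2); R0 <- crossprod(B) + diag(0.1, 2)
    list(grm = grm,
         blues = list(data.frame(line_id = ids[obs1], blue = rnorm(length(obs1))),
                      data.frame(line_id = ids[obs2], blue = rnorm(length(obs2)))),
         G0 = G0, R0 = R0)
  }
}

check_against_oracle <- function(inst) {
  ids <- inst$grm$line_ids
  trait <- integer(0); lidx <- integer(0); y <- numeric(0)
  for (t in seq_along(inst$blues)) {
    b <- inst$blues[[t]]
    trait <- c(trait, rep(t, nrow(b)))
    lidx <- c(lidx, match(b$line_id, ids))
    y <- c(y, b$blue)
  }
  X <- sapply(seq_along(inst$blues), function(t) as.numeric(trait == t))
  V <- oracle_assemble_V(trait, lidx, inst$grm$values, inst$G0, inst$R0)
  ll_or <- oracle_reml_loglik(y, X, V)
  ll_pkg <- if (length(inst$blues) == 1) {
    reml_loglik(inst$blues[[1]], NULL, inst$grm, inst$G0, inst$R0)
  } else {
    reml_loglik(inst$blues[[1]], inst$blues[[2]], inst$grm, inst$G0, inst$R0)
  }
  abs(ll_pkg - ll_or)
}

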