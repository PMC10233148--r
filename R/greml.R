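#' Control parameters for the GREML optimizer
#'
#' @param max_iter maximum number of average-information iterations.
#' @param tol convergence tolerance: iteration stops when the restricted
#'   log-likelihood changes by less than `tol` *and* the largest relative
#'   parameter change is below `tol`.
#' @param var_floor_frac variance parameters are kept at or above this
#'   fraction of the corresponding trait's phenotypic variance.
#' @param verbose print the likelihood path.
#' @return list of class `greml_control`.
#' @export
greml_control <- function(max_iter = 100, tol = 1e-6,
                          var_floor_frac = 1e-8, verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 var_floor_frac = var_floor_frac, verbose = verbose),
            class = "greml_control")
}

## ---- internal: model instance ------------------------------------------

## Stack one or two BLUE tables against a GRM. Records missing for a trait
## are simply absent rows (row omission, never imputation).
greml_instance <- function(blues_list, grm) {
  stopifnot(inherits(grm, "nb_grm"))
  ids <- grm$line_ids
  y <- numeric(0); trait <- integer(0); lidx <- integer(0)
  for (t in seq_along(blues_list)) {
    b <- blues_list[[t]]
    if (is.null(b) || nrow(b) == 0) next
    if (anyDuplicated(b$line_id)) {
      stop_data("duplicate line ids in BLUE table for trait ", t)
    }
    m <- match(b$line_id, ids)
    known <- !is.na(m)
    if (!any(known)) stop_data("no overlap between trait-", t,
                               " phenotyped lines and GRM lines")
    y <- c(y, b$blue[known])
    trait <- c(trait, rep(t, sum(known)))
    lidx <- c(lidx, m[known])
  }
  n_traits <- length(blues_list)
  X <- matrix(0, length(y), n_traits)
  for (t in seq_len(n_traits)) X[trait == t, t] <- 1
  X <- X[, colSums(X) > 0, drop = FALSE]
  ## same-line cross-trait record pairs (for the residual covariance)
  pair_ep <- pair_nir <- integer(0)
  if (n_traits == 2) {
    i1 <- which(trait == 1); i2 <- which(trait == 2)
    m12 <- match(lidx[i1], lidx[i2])
    has <- !is.na(m12)
    pair_ep <- i1[has]
    pair_nir <- i2[m12[has]]
  }
  list(y = y, trait = trait, lidx = lidx, X = X,
       n_traits = n_traits, G = grm$values,
       Gsub = grm$values[lidx, lidx, drop = FALSE],
       same_line = outer(lidx, lidx, "=="),
       pair_ep = pair_ep, pair_nir = pair_nir)
}

theta_to_mats <- function(theta, n_traits) {
  if (n_traits == 1) {
    list(G0 = matrix(theta[1], 1, 1), R0 = matrix(theta[2], 1, 1))
  } else {
    list(G0 = matrix(theta[c(1, 2, 2, 3)], 2, 2),
         R0 = matrix(theta[c(4, 5, 5, 6)], 2, 2))
  }
}

assemble_V <- function(inst, G0, R0) {
  tt <- inst$trait
  inst$Gsub * G0[tt, tt] + inst$same_line * R0[tt, tt]
}

## Full restricted log-likelihood (Harville), including its constants:
##   ll = -1/2 [ log|V| + log|X'V^-1 X| + y'Py + (n-p) log 2pi - log|X'X| ]
## so it equals the exact log-density of any orthonormal set of error
## contrasts K'y ~ N(0, K'VK).
reml_ll_core <- function(y, X, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  n <- length(y); p <- ncol(X)
  Vinv <- chol2inv(ch)
  logdetV <- 2 * sum(log(diag(ch)))
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  chX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  logdetXtVinvX <- 2 * sum(log(diag(chX)))
  P <- Vinv - VinvX %*% chol2inv(chX) %*% t(VinvX)
  Py <- drop(P %*% y)
  yPy <- sum(y * Py)
  logdetXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  ll <- -0.5 * (logdetV + logdetXtVinvX + yPy +
                  (n - p) * log(2 * pi) - as.numeric(logdetXtX))
  list(ll = ll, Vinv = Vinv, P = P, Py = Py, XtVinvX = XtVinvX, VinvX = VinvX)
}

#' Restricted log-likelihood of a (bivariate) GBLUP model
#'
#' Evaluates the exact restricted log-likelihood
#' \deqn{\ell = -\tfrac12\left[\log|V| + \log|X^\top V^{-1} X| + y^\top P y
#'   + (n-p)\log 2\pi - \log|X^\top X|\right]}
#' where \eqn{V} is the phenotypic covariance of the observed records,
#' assembled as the genetic covariance `G0` expanded through the GRM plus
#' the residual covariance `R0` applied within lines, restricted to the
#' observed records, and \eqn{P} is the REML projection matrix. The two
#' trailing constants make this the log-density of orthonormal error
#' contrasts, so values are comparable across parameter sets (same data and
#' fixed-effect design).
#'
#' @param blues_ep BLUE table (`line_id`, `blue`) for the first trait.
#' @param blues_nir optional BLUE table for the second trait (`NULL` for a
#'   single-trait model).
#' @param grm a conditioned [build_grm()] result.
#' @param G0,R0 genetic and residual (co)variance matrices: scalars or 1x1
#'   for a single trait, 2x2 for the bivariate model.
#' @return restricted log-likelihood in nats.
#' @export
reml_loglik <- function(blues_ep, blues_nir = NULL, grm, G0, R0) {
  n_traits <- if (is.null(blues_nir)) 1L else 2L
  inst <- greml_instance(if (n_traits == 1) list(blues_ep)
                         else list(blues_ep, blues_nir), grm)
  G0 <- as.matrix(G0); R0 <- as.matrix(R0)
  V <- assemble_V(inst, G0, R0)
  res <- reml_ll_core(inst$y, inst$X, V)
  if (is.null(res)) {
    stop_compute("phenotypic covariance V is not positive definite for ",
                 "G0 = [", paste(signif(G0, 4), collapse = ", "),
                 "], R0 = [", paste(signif(R0, 4), collapse = ", "), "]")
  }
  res$ll
}

## ---- internal: AI-REML --------------------------------------------------

## Score and average-information pieces for the structured parameters.
## Parameter order: single trait (g, e); bivariate (g11, g12, g22,
## e11, e12, e22). All structure matrices are linear in the parameters.
ai_score_pieces <- function(inst, core) {
  P <- core$P; Py <- core$Py
  n <- length(Py)
  if (inst$n_traits == 1) {
    KPy <- cbind(drop(inst$Gsub %*% Py), Py)
    trPK <- c(sum(P * inst$Gsub), sum(diag(P)))
  } else {
    i1 <- which(inst$trait == 1); i2 <- which(inst$trait == 2)
    KPy <- matrix(0, n, 6)
    KPy[i1, 1] <- inst$Gsub[i1, i1, drop = FALSE] %*% Py[i1]
    KPy[i1, 2] <- inst$Gsub[i1, i2, drop = FALSE] %*% Py[i2]
    KPy[i2, 2] <- inst$Gsub[i2, i1, drop = FALSE] %*% Py[i1]
    KPy[i2, 3] <- inst$Gsub[i2, i2, drop = FALSE] %*% Py[i2]
    KPy[i1, 4] <- Py[i1]
    KPy[inst$pair_ep, 5] <- Py[inst$pair_nir]
    KPy[inst$pair_nir, 5] <- Py[inst$pair_ep]
    KPy[i2, 6] <- Py[i2]
    dP <- diag(P)
    trPK <- c(sum(P[i1, i1] * inst$Gsub[i1, i1]),
              2 * sum(P[i1, i2] * inst$Gsub[i1, i2]),
              sum(P[i2, i2] * inst$Gsub[i2, i2]),
              sum(dP[i1]),
              2 * sum(P[cbind(inst$pair_ep, inst$pair_nir)]),
              sum(dP[i2]))
  }
  score <- -0.5 * (trPK - colSums(KPy * Py))
  AI <- 0.5 * crossprod(KPy, P %*% KPy)
  list(score = score, AI = AI)
}

## Keep theta inside the parameter space: variance floors plus projection
## of G0 / R0 onto the PSD cone (eigenvalue clipping at 1e-8).
constrain_theta <- function(theta, n_traits, floors) {
  clip_psd <- function(M) {
    e <- eigen(M, symmetric = TRUE)
    if (min(e$values) >= 1e-8) return(M)
    e$vectors %*% (pmax(e$values, 1e-8) * t(e$vectors))
  }
  if (n_traits == 1) {
    pmax(theta, floors)
  } else {
    m <- theta_to_mats(theta, 2)
    G0 <- clip_psd(m$G0); R0 <- clip_psd(m$R0)
    th <- c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])
    vloc <- c(1, 3, 4, 6)
    th[vloc] <- pmax(th[vloc], floors[vloc])
    th
  }
}

ai_reml <- function(inst, free = NULL, theta_init = NULL,
                    control = greml_control()) {
  n_traits <- inst$n_traits
  n_par <- if (n_traits == 1) 2L else 6L
  vpar <- if (n_traits == 1) 1:2 else c(1, 3, 4, 6)
  tr_of_vpar <- if (n_traits == 1) c(1, 1) else c(1, 2, 1, 2)
  phen_var <- vapply(seq_len(n_traits),
                     function(t) stats::var(inst$y[inst$trait == t]), 0)
  phen_var[!is.finite(phen_var) | phen_var <= 0] <- 1
  floors <- rep(0, n_par)
  floors[vpar] <- control$var_floor_frac * phen_var[tr_of_vpar]
  if (is.null(free)) free <- rep(TRUE, n_par)
  if (is.null(theta_init)) {
    theta_init <- rep(0, n_par)
    theta_init[vpar] <- 0.5 * phen_var[tr_of_vpar]
  }
  theta <- constrain_theta(theta_init, n_traits, floors)

  eval_theta <- function(th) {
    m <- theta_to_mats(th, n_traits)
    reml_ll_core(inst$y, inst$X, assemble_V(inst, m$G0, m$R0))
  }
  core <- eval_theta(theta)
  if (is.null(core)) stop_compute("starting values give an indefinite V")
  trace <- data.frame(iter = 0L, loglik = core$ll,
                      t(stats::setNames(theta, paste0("theta", seq_len(n_par)))))
  converged <- FALSE
  iter <- 0L
  AI_last <- NULL
  while (iter < control$max_iter) {
    iter <- iter + 1L
    sp <- ai_score_pieces(inst, core)
    AI <- sp$AI[free, free, drop = FALSE]
    AI_last <- sp$AI
    ## light Levenberg damping guards near-singular AI (e.g. G close to I)
    damp <- 1e-8 * mean(diag(AI))
    delta <- rep(0, n_par)
    delta[free] <- tryCatch(
      solve(AI + diag(damp, nrow(AI)), sp$score[free]),
      error = function(e) sp$score[free] * phen_var[1] / length(inst$y)
    )
    ## average-information step with step-halving fallback on any
    ## non-improving proposal
    step <- 1
    improved <- FALSE
    for (h in 1:30) {
      cand <- constrain_theta(theta + step * delta, n_traits, floors)
      core_new <- eval_theta(cand)
      if (!is.null(core_new) && core_new$ll >= core$ll - 1e-12) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {
      converged <- TRUE  # no ascent direction left within machine precision
      break
    }
    d_ll <- core_new$ll - core$ll
    rel <- max(abs(cand - theta) / pmax(abs(theta), 1e-4 * max(phen_var)))
    theta <- cand
    core <- core_new
    trace <- rbind(trace, data.frame(iter = iter, loglik = core$ll,
                                     t(stats::setNames(theta, paste0("theta", seq_len(n_par))))))
    if (control$verbose) {
      message(sprintf("iter %3d  loglik %.6f  (d_ll %.3g)", iter, core$ll, d_ll))
    }
    if (d_ll < control$tol && rel < control$tol) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, core = core, loglik = core$ll, converged = converged,
       n_iter = iter, trace = trace, AI = AI_last, free = free,
       floors = floors)
}

## BLUP of breeding values for every GRM line given a fitted instance.
blup_all_lines <- function(inst, core, G0) {
  b <- solve(core$XtVinvX, crossprod(inst$X, core$Vinv %*% inst$y))
  resid <- inst$y - drop(inst$X %*% b)
  vr <- drop(core$Vinv %*% resid)
  n_lines <- nrow(inst$G)
  u <- matrix(0, n_lines, inst$n_traits)
  for (target in seq_len(inst$n_traits)) {
    for (t in seq_len(inst$n_traits)) {
      rows <- which(inst$trait == t)
      if (length(rows) == 0) next
      u[, target] <- u[, target] + G0[target, t] *
        drop(inst$G[, inst$lidx[rows], drop = FALSE] %*% vr[rows])
    }
  }
  rownames(u) <- rownames(inst$G)
  list(u = u, beta = drop(b))
}

## ---- public fits --------------------------------------------------------

#' Single-trait GREML / GBLUP fit
#'
#' Maximizes the restricted likelihood of
#' \eqn{y = \mu + u + e,\; u \sim N(0, G\sigma^2_g),\; e \sim N(0, I\sigma^2_e)}
#' over \eqn{(\sigma^2_g, \sigma^2_e)} by average-information updates with
#' step-halving on non-improving proposals, then predicts genomic estimated
#' breeding values (GEBVs) for *every* line of the GRM — including
#' unphenotyped lines, which borrow information through their genomic
#' relationships — as
#' \eqn{\hat u = \sigma^2_g G Z^\top V^{-1} (y - X\hat b)}.
#'
#' @param blues BLUE table with columns `line_id` and `blue` (e.g. from
#'   [fit_blues()]).
#' @param grm conditioned GRM covering (at least) the phenotyped lines.
#' @param control a [greml_control()].
#' @return object of class `single_trait_fit`: `sigma2_g`, `sigma2_e`,
#'   `h2`, `loglik`, `converged`, `n_iter`, `gebv` (named vector over all
#'   GRM lines), `mu`, optimizer `trace`, and observed-information standard
#'   errors `se` for the two variance parameters.
#' @export
fit_single_trait <- function(blues, grm, control = greml_control()) {
  inst <- greml_instance(list(blues), grm)
  if (length(inst$y) < 10) {
    stop_data("need at least 10 lines with both a phenotype and a GRM entry (have ",
              length(inst$y), ")")
  }
  fit <- ai_reml(inst, control = control)
  if (!fit$converged) {
    stop_compute("GREML did not converge in ", fit$n_iter, " iterations",
                 trace = fit$trace)
  }
  G0 <- theta_to_mats(fit$theta, 1)$G0
  bl <- blup_all_lines(inst, fit$core, G0)
  se <- tryCatch(sqrt(diag(solve(fit$AI))), error = function(e) rep(NA_real_, 2))
  structure(list(sigma2_g = fit$theta[1], sigma2_e = fit$theta[2],
                 h2 = fit$theta[1] / sum(fit$theta),
                 loglik = fit$loglik, converged = fit$converged,
                 n_iter = fit$n_iter,
                 gebv = stats::setNames(bl$u[, 1], rownames(bl$u)),
                 mu = bl$beta[1], trace = fit$trace, se = se),
            class = "single_trait_fit")
}

#' @export
print.single_trait_fit <- function(x, ...) {
  cat(sprintf("Single-trait GREML fit (%d iterations, %s)\n", x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$h2))
  cat(sprintf("  restricted loglik = %.4f; GEBVs for %d lines\n",
              x$loglik, length(x$gebv)))
  invisible(x)
}

#' Bivariate GREML fit for an end-product trait and its NIR prediction
#'
#' Fits the two-trait GBLUP model with genetic covariance
#' \eqn{G_0 \otimes G} (the 2x2 genetic covariance expanded through the
#' genomic relationship matrix) and unstructured residual covariance
#' \eqn{R_0} applied within lines: the residual covariance couples the two
#' records of a line observed for both traits, while lines observed for a
#' single trait contribute only that trait's residual variance. Records
#' missing for a trait are absent rows of the likelihood, never imputed —
#' this is what lets NIR-only lines contribute to training.
#'
#' If fewer than 2 lines are observed for both traits the residual
#' covariance is not estimable and is fixed at 0 with a warning. If either
#' covariance matrix leaves the positive-semidefinite cone during updates
#' it is projected back by eigenvalue clipping.
#'
#' @param blues_ep,blues_nir BLUE tables for the end-product and
#'   NIR-predicted trait.
#' @param grm conditioned GRM.
#' @param control a [greml_control()].
#' @param r_p_method how to report the phenotypic correlation: `"pearson"`
#'   (Pearson correlation of the two BLUE vectors over lines observed for
#'   both — the default) or `"model"` (derived from `G0 + R0`).
#' @return object of class `bivariate_fit`: `G0`, `R0`, `r_g`, `r_p`,
#'   `h2` (per trait), `loglik`, `converged`, `n_iter`, `gebv_ep`,
#'   `gebv_nir` (all GRM lines), `mu`, `trace`, and observed-information
#'   `se_r_g`.
#' @export
fit_bivariate <- function(blues_ep, blues_nir, grm, control = greml_control(),
                          r_p_method = c("pearson", "model")) {
  r_p_method <- match.arg(r_p_method)
  inst <- greml_instance(list(blues_ep, blues_nir), grm)
  free <- rep(TRUE, 6)
  if (length(inst$pair_ep) < 2) {
    warning("fewer than 2 lines observed for both traits: residual covariance fixed at 0")
    free[5] <- FALSE
  }
  if (!any(inst$trait == 2)) free[c(2, 3, 6)] <- FALSE
  fit <- ai_reml(inst, free = free, control = control)
  if (!fit$converged) {
    stop_compute("bivariate GREML did not converge in ", fit$n_iter,
                 " iterations", trace = fit$trace)
  }
  m <- theta_to_mats(fit$theta, 2)
  bl <- blup_all_lines(inst, fit$core, m$G0)
  r_g <- m$G0[1, 2] / sqrt(m$G0[1, 1] * m$G0[2, 2])
  ## observed-information SE of r_g by the delta method on (g11, g12, g22)
  se_r_g <- tryCatch({
    Vth <- solve(fit$AI[free, free, drop = FALSE])
    full <- matrix(NA_real_, 6, 6)
    full[free, free] <- Vth
    g <- fit$theta[1:3]
    grad <- c(-0.5 * g[2] / (g[1]^1.5 * sqrt(g[3])),
              1 / sqrt(g[1] * g[3]),
              -0.5 * g[2] / (sqrt(g[1]) * g[3]^1.5))
    sqrt(drop(t(grad) %*% full[1:3, 1:3] %*% grad))
  }, error = function(e) NA_real_)
  common <- intersect(blues_ep$line_id, blues_nir$line_id)
  r_p <- if (r_p_method == "model") {
    Ptot <- m$G0 + m$R0
    Ptot[1, 2] / sqrt(Ptot[1, 1] * Ptot[2, 2])
  } else if (length(common) >= 3) {
    stats::cor(blues_ep$blue[match(common, blues_ep$line_id)],
               blues_nir$blue[match(common, blues_nir$line_id)])
  } else {
    NA_real_
  }
  structure(list(G0 = m$G0, R0 = m$R0, r_g = r_g, r_p = r_p,
                 h2 = c(ep = m$G0[1, 1] / (m$G0[1, 1] + m$R0[1, 1]),
                        nir = m$G0[2, 2] / (m$G0[2, 2] + m$R0[2, 2])),
                 loglik = fit$loglik, converged = fit$converged,
                 n_iter = fit$n_iter,
                 gebv_ep = stats::setNames(bl$u[, 1], rownames(bl$u)),
                 gebv_nir = stats::setNames(bl$u[, 2], rownames(bl$u)),
                 mu = bl$beta, trace = fit$trace, se_r_g = se_r_g),
            class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("Bivariate GREML fit (%d iterations, %s)\n", x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  genetic correlation r_g = %.3f (SE %.3f), phenotypic r_p = %.3f\n",
              x$r_g, x$se_r_g, x$r_p))
  cat(sprintf("  h2: EP = %.3f, NIR = %.3f; restricted loglik = %.4f\n",
              x$h2[1], x$h2[2], x$loglik))
  invisible(x)
}

#' Extract GEBVs for a set of lines
#'
#' Returns the BLUP breeding values of the requested lines from a fitted
#' model. Unphenotyped lines carry predictions borrowed through the GRM.
#'
#' @param fit a `single_trait_fit` or `bivariate_fit`.
#' @param target_lines character vector of line ids (must be GRM lines).
#' @param trait for bivariate fits, which trait's GEBVs to return.
#' @return named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, target_lines, trait = c("ep", "nir")) {
  gebv <- if (inherits(fit, "single_trait_fit")) {
    fit$gebv
  } else if (inherits(fit, "bivariate_fit")) {
    if (match.arg(trait) == "ep") fit$gebv_ep else fit$gebv_nir
  } else {
    stop_config("fit must be a single_trait_fit or bivariate_fit")
  }
  unknown <- setdiff(target_lines, names(gebv))
  if (length(unknown) > 0) {
    stop_data("unknown line ids: ", paste(utils::head(unknown, 10), collapse = ", "))
  }
  gebv[target_lines]
}
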