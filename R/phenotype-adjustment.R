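#' Single-pass outlier editing of phenotype records
#'
#' For each trait, computes the mean and standard deviation once over all of
#' that trait's records and removes records further than 4 SD from the mean.
#' There is no iteration and no stratification by trial: moments are global
#' per trait, so a single extreme value can inflate the SD enough to protect
#' itself in tiny samples — the edit is a coarse screen for gross assay or
#' transcription errors, not a robust filter.
#'
#' @param table long-format phenotype data.frame with columns `trait` and
#'   `value` (see [simulate_phenotypes()] for the full dialect).
#' @param n_sd threshold in standard deviations (default 4).
#' @return list with `table` (retained records) and `removed` (the audited
#'   removals, same columns).
#' @export
edit_outliers <- function(table, n_sd = 4) {
  keep <- rep(TRUE, nrow(table))
  for (tr in unique(table$trait)) {
    idx <- which(table$trait == tr)
    v <- table$value[idx]
    if (length(v) < 2) next
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) next
    keep[idx[abs(v - mean(v)) > n_sd * s]] <- FALSE
  }
  list(table = table[keep, , drop = FALSE],
       removed = table[!keep, , drop = FALSE])
}

trial_key <- function(table) {
  paste(table$year, table$location, table$nursery, sep = "_")
}

## Connected components of the bipartite line x trial graph.
design_components <- function(line, trial) {
  g <- igraph::graph_from_edgelist(
    cbind(paste0("line::", line), paste0("trial::", trial)),
    directed = FALSE
  )
  comp <- igraph::components(g)
  membership <- comp$membership[paste0("line::", unique(line))]
  names(membership) <- unique(line)
  list(n = comp$no, line_membership = membership)
}

#' Per-line BLUEs from unbalanced multi-trial records
#'
#' Fits the two-way fixed-effect model `value = mean + trial + line + error`
#' by least squares, where *trial* is the concatenated
#' year-location-nursery group. Corner-point constraints are used (first
#' trial and first line as reference), and the reported BLUE of a line is
#' the intercept plus its line effect, so in a single-trial design BLUEs
#' equal the raw values and line differences are invariant to the choice of
#' reference.
#'
#' The line-by-trial design must be connected (one component of the
#' bipartite incidence graph); otherwise BLUEs are not comparable across
#' components and an error names them. A line confounded with its own trial
#' (the only line of a trial, appearing in no other trial) is not separable
#' from the trial effect: its raw mean is reported with an infinite
#' standard error and a warning.
#'
#' @param table long-format phenotype data.frame.
#' @param trait trait label to adjust.
#' @return data.frame (one row per line): `line_id`, `trait`, `blue`, `se`,
#'   `n_records`.
#' @export
fit_blues <- function(table, trait) {
  d <- table[table$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop_data("no records for trait '", trait, "'")
  d$trial <- trial_key(d)

  ## lines confounded with a singleton trial (only line of that trial,
  ## present nowhere else) are screened out first: they are their own
  ## degenerate component and get a raw mean with infinite SE below
  conf <- character(0)
  tl <- unique(d[, c("line_id", "trial")])
  lines_per_trial <- table(tl$trial)
  trials_per_line <- table(tl$line_id)
  for (tr in names(lines_per_trial)[lines_per_trial == 1]) {
    ln <- tl$line_id[tl$trial == tr]
    if (trials_per_line[[ln]] == 1) conf <- c(conf, ln)
  }
  est <- d[!(d$line_id %in% conf), , drop = FALSE]

  if (nrow(est) > 0) {
    comp <- design_components(est$line_id, est$trial)
    if (comp$n > 1) {
      sizes <- table(comp$line_membership)
      stop_data("line-by-trial design is disconnected (", comp$n,
                " components with ", paste(sizes, collapse = ", "),
                " lines); BLUEs are not comparable across components")
    }
  }

  blue <- se <- stats::setNames(numeric(0), character(0))
  if (nrow(est) > 0) {
    f_trial <- factor(est$trial)
    f_line <- factor(est$line_id)
    form <- if (nlevels(f_trial) > 1 && nlevels(f_line) > 1) {
      ~ f_trial + f_line
    } else if (nlevels(f_line) > 1) {
      ~ f_line
    } else if (nlevels(f_trial) > 1) {
      ~ f_trial
    } else {
      ~ 1
    }
    X <- Matrix::sparse.model.matrix(form)
    XtX <- Matrix::crossprod(X)
    Xty <- Matrix::crossprod(X, est$value)
    beta <- tryCatch(as.numeric(Matrix::solve(XtX, Xty)),
                     error = function(e) {
                       stop_compute("singular BLUE design: ", conditionMessage(e))
                     })
    names(beta) <- colnames(X)
    fitted <- as.numeric(X %*% beta)
    rdf <- nrow(est) - ncol(X)
    s2 <- if (rdf > 0) sum((est$value - fitted)^2) / rdf else 0
    XtX_inv <- as.matrix(Matrix::solve(XtX))
    lev <- levels(f_line)
    blue <- se <- stats::setNames(numeric(length(lev)), lev)
    for (i in seq_along(lev)) {
      cvec <- numeric(ncol(X))
      cvec[1] <- 1
      if (i > 1) cvec[match(paste0("f_line", lev[i]), colnames(X))] <- 1
      blue[i] <- sum(cvec * beta)
      se[i] <- sqrt(s2 * drop(t(cvec) %*% XtX_inv %*% cvec))
    }
  }
  if (length(conf) > 0) {
    warning("lines confounded with a singleton trial (BLUE = raw mean, SE = Inf): ",
            paste(conf, collapse = ", "))
    raw <- vapply(conf, function(ln) mean(d$value[d$line_id == ln]), 0)
    blue <- c(blue, raw)
    se <- c(se, stats::setNames(rep(Inf, length(conf)), conf))
  }
  nrec <- table(d$line_id)
  out <- data.frame(line_id = names(blue), trait = trait,
                    blue = unname(blue), se = unname(se),
                    n_records = as.integer(nrec[names(blue)]),
                    row.names = NULL)
  out[order(out$line_id), , drop = FALSE]
}

#' Line variance components for broad-sense heritability
#'
#' Fits `value = mean + trial (fixed) + line (random) + error` by REML
#' (via \pkg{lme4}) and returns the line and residual variances together
#' with the design summaries that enter the line-mean heritability:
#' `T`, the mean number of distinct trials per line, and `R`, the mean
#' number of replicate records per line-by-trial cell.
#'
#' @param table long-format phenotype data.frame.
#' @param trait trait label.
#' @return object of class `line_variance`: list with `sigma2_g`,
#'   `sigma2_e`, `T`, `R`, `H2` (from [broad_h2()]) and the fitted model.
#' @export
estimate_line_variance <- function(table, trait) {
  d <- table[table$trait == trait, , drop = FALSE]
  if (length(unique(d$line_id)) < 2) {
    stop_data("need records on at least two lines")
  }
  d$trial <- trial_key(d)
  d$line_id <- factor(d$line_id)
  fit <- if (length(unique(d$trial)) > 1) {
    lme4::lmer(value ~ trial + (1 | line_id), data = d, REML = TRUE)
  } else {
    lme4::lmer(value ~ 1 + (1 | line_id), data = d, REML = TRUE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2_g <- vc$vcov[vc$grp == "line_id"]
  sigma2_e <- vc$vcov[vc$grp == "Residual"]
  per_line_trials <- tapply(d$trial, d$line_id, function(x) length(unique(x)))
  t_mean <- mean(per_line_trials)
  reps <- stats::aggregate(value ~ line_id + trial, d, length)$value
  r_mean <- mean(reps)
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 T = t_mean, R = r_mean,
                 H2 = broad_h2(sigma2_g, sigma2_e, t_mean, r_mean),
                 model = fit),
            class = "line_variance")
}

#' @export
print.line_variance <- function(x, ...) {
  cat(sprintf("Line variance components: sigma2_g = %.4g, sigma2_e = %.4g\n",
              x$sigma2_g, x$sigma2_e))
  cat(sprintf("  T = %.2f trials/line, R = %.2f reps/line-trial, H2 = %.3f\n",
              x$T, x$R, x$H2))
  invisible(x)
}

#' Broad-sense heritability on a line-mean basis
#'
#' \deqn{H^2 = \sigma^2_g / \left(\sigma^2_g + \sigma^2_e / (T R)\right)}
#' where \eqn{\sigma^2_g} and \eqn{\sigma^2_e} are the line and residual
#' variances and `T` and `R` are the mean numbers of trials and of
#' replications per line. With `T = R = 1` this is the plot-level
#' repeatability.
#'
#' @param sigma2_g,sigma2_e line and residual variance (trait units
#'   squared), both `>= 0`.
#' @param T,R mean trials per line and mean replications per line-trial;
#'   their product must be positive.
#' @return heritability in `[0, 1]`.
#' @export
#' @examples
#' broad_h2(0.86, 0.13)  # 0.869
broad_h2 <- function(sigma2_g, sigma2_e, T = 1, R = 1) {
  if (sigma2_g < 0 || sigma2_e < 0) stop_config("variances must be >= 0")
  if (T * R <= 0) stop_config("T * R must be positive")
  if (sigma2_g == 0 && sigma2_e == 0) {
    stop_compute("heritability undefined: both variances are zero")
  }
  sigma2_g / (sigma2_g + sigma2_e / (T * R))
}
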