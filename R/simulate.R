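#' Simulation configuration for a synthetic breeding program
#'
#' Bundles every knob of the synthetic data generator: genome size, allele
#' frequency spectrum, the genetic architecture of the trait pair
#' (an end-product quality trait assayed in the laboratory and its
#' NIR-predicted counterpart), and the multi-year trial design.
#'
#' Phenotypes are generated on a unit phenotypic variance scale per trait:
#' the additive genetic variance of trait \eqn{t} equals its heritability
#' \eqn{h^2_t} and the residual variance equals \eqn{1 - h^2_t}, so the
#' generating parameters are directly comparable with REML estimates on
#' adjusted phenotypes.
#'
#' Default genetic parameters follow published estimates for crumb
#' yellowness in a commercial wheat program (SNP heritability 0.68 for the
#' laboratory assay, genetic correlation 0.83 with its NIR prediction);
#' the trial design defaults (two trials per year, 15% of lines carried
#' over to the next year) are typical of early-generation quality testing
#' and guarantee a connected line-by-trial design.
#'
#' @param n_lines number of breeding lines to simulate.
#' @param n_markers number of biallelic SNP markers.
#' @param maf_range length-2 numeric, range of alternate-allele frequencies
#'   drawn per marker (uniform). Must lie in (0, 1]; values above 0.5 are
#'   allowed so fixation edge cases can be exercised.
#' @param h2_ep,h2_nir narrow-sense heritabilities of the end-product and
#'   NIR-predicted traits, in `[0, 1]`.
#' @param r_g,r_e genetic and residual correlations between the two traits,
#'   in `[-1, 1]`.
#' @param years vector of year labels (coerced to character).
#' @param lines_per_year_ep,lines_per_year_nir optional integer vectors
#'   (same length as `years`) giving, per year, the number of lines retained
#'   with end-product / NIR records by [apply_missingness()]. `NULL` keeps
#'   every simulated record.
#' @param n_trials_per_year number of trials in each year.
#' @param trial_effect_sd standard deviation of the fixed trial effect
#'   (trait units), drawn independently per trial and trait.
#' @param carryover_frac fraction of each year's cohort that is also grown
#'   in the following year; connects the design across years.
#' @param n_families if positive, lines are grouped into half-sib families
#'   that share one parental haplotype, creating relatedness structure.
#'   Off (0) by default.
#' @param mean_ep,mean_nir trait means (trait units).
#' @param trait_ep,trait_nir trait labels used in the phenotype table.
#' @param seed master seed; all generator randomness derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 50, n_markers = 100, years = 2012:2013)
sim_config <- function(n_lines,
                       n_markers,
                       maf_range = c(0.05, 0.5),
                       h2_ep = 0.68,
                       h2_nir = 0.68,
                       r_g = 0.83,
                       r_e = 0.30,
                       years = 2012:2019,
                       lines_per_year_ep = NULL,
                       lines_per_year_nir = NULL,
                       n_trials_per_year = 2,
                       trial_effect_sd = 1,
                       carryover_frac = 0.15,
                       n_families = 0,
                       mean_ep = 0,
                       mean_nir = 0,
                       trait_ep = "EP",
                       trait_nir = "NIR",
                       seed = 1) {
  if (n_lines < 2 || n_markers < 1) {
    stop_config("need n_lines >= 2 and n_markers >= 1")
  }
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 1 || maf_range[1] > maf_range[2]) {
    stop_config("maf_range must be an increasing pair in (0, 1]")
  }
  for (h2 in c(h2_ep, h2_nir)) {
    if (!is.finite(h2) || h2 < 0 || h2 > 1) {
      stop_config("heritabilities must lie in [0, 1]")
    }
  }
  if (abs(r_g) > 1 || abs(r_e) > 1) {
    stop_config("correlations must lie in [-1, 1]")
  }
  years <- as.character(years)
  for (nm in c("lines_per_year_ep", "lines_per_year_nir")) {
    counts <- get(nm)
    if (!is.null(counts)) {
      if (length(counts) != length(years) || any(counts < 0)) {
        stop_config(nm, " must give one non-negative count per year")
      }
    }
  }
  if (n_trials_per_year < 1) stop_config("need at least one trial per year")
  if (carryover_frac < 0 || carryover_frac >= 1) {
    stop_config("carryover_frac must lie in [0, 1)")
  }
  ## implied 2x2 genetic / residual covariance matrices (unit phenotypic
  ## variance scale); PSD holds by construction when |r| <= 1, checked anyway
  Sg <- outer(sqrt(c(h2_ep, h2_nir)), sqrt(c(h2_ep, h2_nir))) *
    matrix(c(1, r_g, r_g, 1), 2)
  Se <- outer(sqrt(1 - c(h2_ep, h2_nir)), sqrt(1 - c(h2_ep, h2_nir))) *
    matrix(c(1, r_e, r_e, 1), 2)
  if (min(eigen(Sg, symmetric = TRUE, only.values = TRUE)$values) < -1e-12 ||
      min(eigen(Se, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop_config("implied trait covariance matrices are not positive semidefinite")
  }
  structure(list(
    n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
    maf_range = maf_range, h2_ep = h2_ep, h2_nir = h2_nir,
    r_g = r_g, r_e = r_e, years = years,
    lines_per_year_ep = lines_per_year_ep,
    lines_per_year_nir = lines_per_year_nir,
    n_trials_per_year = as.integer(n_trials_per_year),
    trial_effect_sd = trial_effect_sd,
    carryover_frac = carryover_frac, n_families = as.integer(n_families),
    mean_ep = mean_ep, mean_nir = mean_nir,
    trait_ep = trait_ep, trait_nir = trait_nir,
    Sg = Sg, Se = Se, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic breeding-program configuration\n")
  cat(sprintf("  %d lines x %d markers, MAF in [%.2f, %.2f]\n",
              x$n_lines, x$n_markers, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  h2: %s=%.2f, %s=%.2f; r_g=%.2f, r_e=%.2f\n",
              x$trait_ep, x$h2_ep, x$trait_nir, x$h2_nir, x$r_g, x$r_e))
  cat(sprintf("  %d years (%s..%s), %d trial(s)/year, seed %d\n",
              length(x$years), x$years[1], x$years[length(x$years)],
              x$n_trials_per_year, x$seed))
  invisible(x)
}

safe_sample <- function(x, k) x[sample.int(length(x), k)]

#' Simulate SNP dosage genotypes
#'
#' Draws per-marker alternate-allele frequencies uniformly from
#' `config$maf_range` and samples dosages as binomial(2, p) per line
#' (Hardy-Weinberg sampling). With `n_families > 0`, lines within a family
#' share one parental transmitted haplotype, which induces half-sib
#' relatedness visible in the genomic relationship matrix.
#'
#' @param config a [sim_config()].
#' @return integer matrix (`n_lines` x `n_markers`, dosages in 0/1/2) with
#'   line ids as rownames and marker ids as colnames; drawn allele
#'   frequencies attached as attribute `"freq_drawn"`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines
  m <- config$n_markers
  with_local_seed(child_seed(config$seed, 1L), {
    p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    if (config$n_families > 0) {
      ## contiguous family blocks, so families align with year cohorts and
      ## relatedness turns over across breeding cycles
      fam <- rep(seq_len(config$n_families),
                 each = ceiling(n / config$n_families))[seq_len(n)]
      X <- matrix(0L, n, m)
      for (j in seq_len(m)) {
        parent_hap <- stats::rbinom(config$n_families, 1L, p[j])
        X[, j] <- parent_hap[fam] + stats::rbinom(n, 1L, p[j])
      }
    } else {
      X <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
    }
    dimnames(X) <- list(sprintf("L%04d", seq_len(n)),
                        sprintf("M%05d", seq_len(m)))
    attr(X, "freq_drawn") <- p
    X
  })
}

## Symmetric matrix square root (2x2 use here, but general).
sym_sqrt <- function(M, inverse = FALSE) {
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (inverse) {
    pos <- lam > max(lam, 1) * 1e-12
    lam[pos] <- 1 / sqrt(lam[pos])
    lam[!pos] <- 0
  } else {
    lam <- sqrt(lam)
  }
  e$vectors %*% (lam * t(e$vectors))
}

## Assign lines to year cohorts honouring any per-year retention pattern.
assign_cohorts <- function(config) {
  n <- config$n_lines
  yrs <- config$years
  need <- rep(0L, length(yrs))
  if (!is.null(config$lines_per_year_ep)) {
    need <- pmax(need, as.integer(config$lines_per_year_ep))
  }
  if (!is.null(config$lines_per_year_nir)) {
    need <- pmax(need, as.integer(config$lines_per_year_nir))
  }
  if (sum(need) > n) {
    stop_config("per-year line counts (", sum(need),
                ") exceed n_lines (", n, ")")
  }
  if (all(need == 0L)) {
    base <- n %/% length(yrs)
    need <- rep(base, length(yrs))
    extra <- n - sum(need)
    if (extra > 0) need[seq_len(extra)] <- need[seq_len(extra)] + 1L
  } else {
    ## spread any leftover lines round-robin so every line is phenotyped
    leftover <- n - sum(need)
    if (leftover > 0) {
      add <- tabulate(rep_len(seq_along(yrs), leftover), length(yrs))
      need <- need + add
    }
  }
  split(seq_len(n), factor(rep(seq_along(yrs), need), levels = seq_along(yrs)))
}

#' Simulate bivariate trial phenotypes with known genetic truth
#'
#' Breeding values are built from the centred dosage matrix and a pair of
#' per-marker effect vectors drawn from a bivariate normal, then linearly
#' transformed so the *realized* (sample) genetic variances and correlation
#' hit the configured `h2_ep`, `h2_nir` and `r_g` exactly — the returned
#' truth is exact at any sample size, which is what makes tight
#' parameter-recovery tests possible. Residual pairs are drawn bivariate
#' normal with correlation `r_e` per line-by-trial record; trial effects are
#' i.i.d. normal per (year, trial, trait) and shared by all records in the
#' trial, giving an estimable fixed trial structure. NIR instrument error is
#' part of the NIR trait's residual: the NIR prediction is modelled as a
#' second correlated trait, not derived from spectra.
#'
#' Each line belongs to one cohort year (plus an optional carryover into the
#' next year); within a year lines are spread round-robin across trials and
#' neighbouring trials are bridged by one shared line, so the line-by-trial
#' incidence graph is connected.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()] (no missing).
#' @param config the same [sim_config()].
#' @return list with `phenotypes` (long-format data.frame: `record_id`,
#'   `line_id`, `year`, `location`, `nursery`, `trait`, `value`) and
#'   `truth` (class `sim_truth`: per-line breeding values for both traits,
#'   marker effects, and the generating parameters).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(genotypes)) stop_data("genotypes must be complete (no missing dosages)")
  n <- nrow(genotypes)
  if (n != config$n_lines) stop_config("genotype rows do not match config n_lines")
  line_ids <- rownames(genotypes)

  with_local_seed(child_seed(config$seed, 2L), {
    W <- scale(genotypes, center = TRUE, scale = FALSE)
    a <- matrix(stats::rnorm(ncol(W) * 2), ncol(W), 2)
    u <- W %*% a
    ## transform to exact realized genetic covariance
    h2 <- c(config$h2_ep, config$h2_nir)
    if (abs(config$r_g) == 1 || any(h2 == 0)) {
      ## degenerate targets: scale trait 1, derive trait 2 proportionally
      s1 <- stats::sd(u[, 1])
      u[, 1] <- if (s1 > 0) u[, 1] * sqrt(h2[1]) / s1 else 0
      a[, 1] <- if (s1 > 0) a[, 1] * sqrt(h2[1]) / s1 else 0
      if (abs(config$r_g) == 1 && all(h2 > 0)) {
        scl <- sign(config$r_g) * sqrt(h2[2] / h2[1])
        u[, 2] <- u[, 1] * scl
        a[, 2] <- a[, 1] * scl
      } else {
        s2 <- stats::sd(u[, 2])
        u[, 2] <- if (s2 > 0 && h2[2] > 0) u[, 2] * sqrt(h2[2]) / s2 else 0
        a[, 2] <- if (s2 > 0 && h2[2] > 0) a[, 2] * sqrt(h2[2]) / s2 else 0
      }
    } else {
      Tm <- sym_sqrt(config$Sg) %*% sym_sqrt(stats::cov(u), inverse = TRUE)
      u <- u %*% t(Tm)
      a <- a %*% t(Tm)
    }
    colnames(u) <- colnames(a) <- c(config$trait_ep, config$trait_nir)

    ## trial layout
    cohorts <- assign_cohorts(config)
    yrs <- config$years
    nT <- config$n_trials_per_year
    locations <- c("NSW", "VIC", "WA", "SA")
    recs <- vector("list", length(yrs))
    Le <- chol_psd(config$Se)
    for (yi in seq_along(yrs)) {
      obs <- cohorts[[yi]]
      if (yi > 1 && config$carryover_frac > 0) {
        prev <- cohorts[[yi - 1]]
        k <- ceiling(config$carryover_frac * length(prev))
        obs <- c(obs, prev[seq_len(min(k, length(prev)))])
      }
      if (length(obs) == 0) next
      trial_of <- rep_len(seq_len(nT), length(obs))
      pairs <- data.frame(line = obs, trial = trial_of)
      if (nT >= 2) {
        ## bridge neighbouring trials with one shared line each
        for (t in seq_len(nT)) {
          first <- obs[which(trial_of == t)[1]]
          if (!is.na(first)) {
            pairs <- rbind(pairs, data.frame(line = first, trial = t %% nT + 1L))
          }
        }
        pairs <- unique(pairs)
      }
      t_eff <- matrix(stats::rnorm(nT * 2, 0, config$trial_effect_sd), nT, 2)
      loc <- safe_sample(rep_len(locations, nT), nT)
      e <- matrix(stats::rnorm(nrow(pairs) * 2), nrow(pairs), 2) %*% Le
      mu <- c(config$mean_ep, config$mean_nir)
      for (t in 1:2) {
        recs[[yi]] <- rbind(recs[[yi]], data.frame(
          line_id = line_ids[pairs$line],
          year = yrs[yi],
          location = loc[pairs$trial],
          nursery = sprintf("N%02d", pairs$trial),
          trait = colnames(u)[t],
          value = mu[t] + t_eff[pairs$trial, t] + u[pairs$line, t] + e[, t],
          stringsAsFactors = FALSE
        ))
      }
    }
    pheno <- do.call(rbind, recs)
    rownames(pheno) <- NULL
    pheno <- cbind(record_id = seq_len(nrow(pheno)), pheno)

    truth <- structure(list(
      true_bv = data.frame(line_id = line_ids, bv_ep = u[, 1], bv_nir = u[, 2],
                           row.names = NULL),
      marker_effects = a,
      true_params = list(h2_ep = config$h2_ep, h2_nir = config$h2_nir,
                         r_g = config$r_g, r_e = config$r_e,
                         Sg = config$Sg, Se = config$Se)
    ), class = "sim_truth")
    list(phenotypes = pheno, truth = truth)
  })
}

## Cholesky-like factor that tolerates PSD (singular) matrices.
chol_psd <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
}

#' Thin phenotype records to an unbalanced multi-year design
#'
#' Retains, for each year, the configured number of lines with end-product
#' records (`lines_per_year_ep`) and with NIR records (`lines_per_year_nir`),
#' dropping all records of the other lines for that (year, trait). NIR
#' retention preferentially keeps the lines already retained for the
#' end-product assay, so lines observed for both traits form the overlap the
#' paired-training cross-validation scenario needs. Selection is
#' deterministic under the configuration seed. In single-trial designs
#' without carryover each retained line contributes exactly one record per
#' (year, trait), so retained record counts equal the configured line
#' counts.
#'
#' @param table long-format phenotype data.frame from [simulate_phenotypes()].
#' @param config the [sim_config()]; a `NULL` count vector leaves that trait
#'   untouched.
#' @return the thinned phenotype data.frame.
#' @export
apply_missingness <- function(table, config) {
  stopifnot(inherits(config, "sim_config"))
  kept <- rep(TRUE, nrow(table))
  with_local_seed(child_seed(config$seed, 3L), {
    sel <- list()
    for (yi in seq_along(config$years)) {
      y <- config$years[yi]
      ep_avail <- unique(table$line_id[table$year == y &
                                         table$trait == config$trait_ep])
      nir_avail <- unique(table$line_id[table$year == y &
                                          table$trait == config$trait_nir])
      keep_ep <- ep_avail
      if (!is.null(config$lines_per_year_ep)) {
        k <- config$lines_per_year_ep[yi]
        if (k > length(ep_avail)) {
          stop_config("year ", y, ": requested ", k, " end-product lines but only ",
                      length(ep_avail), " available")
        }
        keep_ep <- safe_sample(ep_avail, k)
        kept[table$year == y & table$trait == config$trait_ep &
               !(table$line_id %in% keep_ep)] <- FALSE
      }
      if (!is.null(config$lines_per_year_nir)) {
        k <- config$lines_per_year_nir[yi]
        if (k > length(nir_avail)) {
          stop_config("year ", y, ": requested ", k, " NIR lines but only ",
                      length(nir_avail), " available")
        }
        overlap <- intersect(keep_ep, nir_avail)
        if (k <= length(overlap)) {
          keep_nir <- safe_sample(overlap, k)
        } else {
          rest <- setdiff(nir_avail, overlap)
          keep_nir <- c(overlap, safe_sample(rest, k - length(overlap)))
        }
        kept[table$year == y & table$trait == config$trait_nir &
               !(table$line_id %in% keep_nir)] <- FALSE
      }
    }
  })
  out <- table[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulation ground truth: %d lines, %d markers\n",
              nrow(x$true_bv), nrow(x$marker_effects)))
  cat(sprintf("  generating h2 = (%.2f, %.2f), r_g = %.2f, r_e = %.2f\n",
              x$true_params$h2_ep, x$true_params$h2_nir,
              x$true_params$r_g, x$true_params$r_e))
  invisible(x)
}
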