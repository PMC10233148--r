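#' Fivefold cross-validation fold assignments
#'
#' Builds, for each repeat, a fresh random partition of the supplied lines
#' into `k` near-equal folds (sizes differ by at most one). All records of
#' a line travel together: folds are line-level, which prevents within-line
#' leakage between training and validation. The plan is deterministic under
#' the master seed, with each repeat drawing from its own derived
#' substream.
#'
#' @param lines character vector of line ids to partition (typically the
#'   end-product-phenotyped lines).
#' @param k number of folds (>= 2).
#' @param repeats number of repeated partitions.
#' @param seed master seed.
#' @return object of class `mask_plan`: list with `lines`, `k`, `repeats`,
#'   `seed` and `folds` — a list of `repeats` integer vectors (fold index
#'   1..k, named by line id).
#' @export
make_folds <- function(lines, k = 5, repeats = 10, seed = 1) {
  lines <- as.character(lines)
  if (k < 2) stop_config("k must be >= 2")
  if (length(lines) < k) {
    stop_config("fewer lines (", length(lines), ") than folds (", k, ")")
  }
  if (anyDuplicated(lines)) stop_config("duplicate line ids")
  folds <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds[[r]] <- with_local_seed(child_seed(seed, 100L + r), {
      stats::setNames(rep_len(seq_len(k), length(lines))[sample.int(length(lines))],
                      lines)
    })
  }
  structure(list(lines = lines, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 folds = folds),
            class = "mask_plan")
}

#' @export
print.mask_plan <- function(x, ...) {
  cat(sprintf("Mask plan: %d lines, %d folds x %d repeats (seed %d)\n",
              length(x$lines), x$k, x$repeats, x$seed))
  invisible(x)
}

#' Build masked training sets for one fold under a scenario
#'
#' Scenarios govern which NIR-predicted records accompany the end-product
#' training data:
#' \describe{
#'   \item{S0}{single-trait baseline: training uses the non-validation
#'     end-product BLUEs only; NIR data are unused.}
#'   \item{S1}{paired training: end-product and NIR training records are
#'     both restricted to non-validation lines observed for *both* traits;
#'     the validation lines' records of both traits are removed.}
#'   \item{S2}{as S1, plus all NIR-only lines (lines with NIR but no
#'     end-product record) are added to the NIR training set; validation
#'     lines' NIR records stay masked.}
#'   \item{S3}{as S2, but the validation lines' own NIR records are
#'     retained in training — the "NIR-phenotype the candidates early"
#'     design.}
#' }
#' The held-out end-product truth is returned separately and never enters
#' any training structure; this is asserted on every call and a violation
#' is a hard internal error.
#'
#' @param plan a [make_folds()] plan built on end-product-phenotyped lines.
#' @param fold fold index in `1..k`.
#' @param rep_idx repeat index in `1..repeats`.
#' @param blues_ep,blues_nir BLUE tables (`line_id`, `blue`).
#' @param scenario one of `"S0"`, `"S1"`, `"S2"`, `"S3"`.
#' @return list with `train_ep`, `train_nir` (BLUE tables; `train_nir` has
#'   zero rows under S0), `truth_ep` (validation lines' BLUEs) and
#'   `val_lines`.
#' @export
apply_scenario <- function(plan, fold, rep_idx, blues_ep, blues_nir = NULL,
                           scenario = c("S0", "S1", "S2", "S3")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(plan, "mask_plan"))
  assign <- plan$folds[[rep_idx]]
  val_lines <- names(assign)[assign == fold]
  if (!all(val_lines %in% blues_ep$line_id)) {
    stop_data("validation lines must all have end-product records")
  }
  ep_lines <- blues_ep$line_id
  nir_lines <- if (is.null(blues_nir)) character(0) else blues_nir$line_id
  both <- intersect(ep_lines, nir_lines)
  nir_only <- setdiff(nir_lines, ep_lines)

  if (scenario == "S0") {
    tr_ep <- setdiff(ep_lines, val_lines)
    tr_nir <- character(0)
  } else if (scenario == "S1") {
    tr_ep <- setdiff(both, val_lines)
    tr_nir <- tr_ep
  } else if (scenario == "S2") {
    tr_ep <- setdiff(both, val_lines)
    tr_nir <- c(tr_ep, nir_only)
  } else {
    tr_ep <- setdiff(both, val_lines)
    tr_nir <- c(tr_ep, nir_only, intersect(val_lines, nir_lines))
  }
  if (length(intersect(tr_ep, val_lines)) > 0) {
    stop("internal consistency failure: validation end-product value in training")
  }
  out <- list(
    train_ep = blues_ep[blues_ep$line_id %in% tr_ep, , drop = FALSE],
    train_nir = if (is.null(blues_nir)) {
      NULL
    } else {
      blues_nir[blues_nir$line_id %in% tr_nir, , drop = FALSE]
    },
    truth_ep = blues_ep[blues_ep$line_id %in% val_lines, , drop = FALSE],
    val_lines = val_lines, scenario = scenario
  )
  if (any(out$truth_ep$line_id %in% out$train_ep$line_id)) {
    stop("internal consistency failure: validation end-product value in training")
  }
  out
}

#' Cross-validated genomic prediction accuracy under scenarios S0-S3
#'
#' For every (scenario, repeat, fold): builds the masked training sets with
#' [apply_scenario()], fits a single-trait (S0) or bivariate (S1-S3) GREML
#' model, predicts the validation lines' end-product GEBVs, and scores the
#' Pearson correlation between GEBVs and the held-out end-product BLUEs.
#' A fold whose REML fit fails to converge is recorded as failed, excluded
#' from the mean and counted in the report. The whole procedure is
#' deterministic given the plan and inputs.
#'
#' @param blues_ep,blues_nir BLUE tables.
#' @param grm conditioned GRM covering all lines involved.
#' @param plan a [make_folds()] plan over the end-product lines.
#' @param scenarios subset of `c("S0","S1","S2","S3")`.
#' @param control a [greml_control()].
#' @return object of class `accuracy_report`: `folds` (tidy data.frame:
#'   scenario, trait, rep, fold, n_val, r, converged), `summary` (per
#'   scenario: mean, sd, n_folds, n_failed).
#' @export
run_cv <- function(blues_ep, blues_nir = NULL, grm, plan,
                   scenarios = c("S0", "S1", "S2", "S3"),
                   control = greml_control()) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  rows <- list()
  for (sc in scenarios) {
    for (r in seq_len(plan$repeats)) {
      for (f in seq_len(plan$k)) {
        sets <- apply_scenario(plan, f, r, blues_ep, blues_nir, sc)
        res <- tryCatch({
          fit <- if (sc == "S0") {
            fit_single_trait(sets$train_ep, grm, control)
          } else {
            fit_bivariate(sets$train_ep, sets$train_nir, grm, control)
          }
          gebv <- predict_gebv(fit, sets$truth_ep$line_id, trait = "ep")
          list(r = stats::cor(gebv, sets$truth_ep$blue), converged = TRUE)
        }, error = function(e) list(r = NA_real_, converged = FALSE))
        rows[[length(rows) + 1]] <- data.frame(
          scenario = sc, trait = "ep", rep = r, fold = f,
          n_val = length(sets$val_lines), r = res$r, converged = res$converged
        )
      }
    }
  }
  folds <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(folds, folds$scenario), function(d) {
    data.frame(scenario = d$scenario[1],
               mean = mean(d$r[d$converged], na.rm = TRUE),
               sd = stats::sd(d$r[d$converged]),
               n_folds = nrow(d), n_failed = sum(!d$converged))
  }))
  rownames(summ) <- NULL
  structure(list(folds = folds, summary = summ, type = "cv"),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Prediction accuracy report (%s)\n", x$type))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' First observation year of each line
#'
#' @param table long-format phenotype data.frame with `line_id` and `year`.
#' @return data.frame `line_id`, `first_year`.
#' @export
line_first_year <- function(table) {
  fy <- tapply(as.character(table$year), table$line_id, min)
  data.frame(line_id = names(fy), first_year = unname(fy), row.names = NULL)
}

#' Train/validation split for forward prediction
#'
#' Training lines are those first observed in `train_years`; the validation
#' set holds the end-product-phenotyped lines first observed in
#' `test_year`. A line observed in both periods is, by its first
#' observation year, a training member and is excluded from validation.
#'
#' @param blues_ep,blues_nir BLUE tables.
#' @param line_years data.frame from [line_first_year()].
#' @param train_years vector of training year labels.
#' @param test_year single test year label (not in `train_years`).
#' @param mode `"multi"`: training includes all NIR BLUEs of training-year
#'   lines; `"single"`: end-product records only.
#' @return list with `train_ep`, `train_nir`, `truth_ep`, `val_lines`.
#' @export
forward_split <- function(blues_ep, blues_nir = NULL, line_years,
                          train_years, test_year,
                          mode = c("multi", "single")) {
  mode <- match.arg(mode)
  train_years <- as.character(train_years)
  test_year <- as.character(test_year)
  if (test_year %in% train_years) {
    stop_config("test year must not be a training year")
  }
  tr_lines <- line_years$line_id[line_years$first_year %in% train_years]
  val_lines <- intersect(
    line_years$line_id[line_years$first_year == test_year],
    blues_ep$line_id
  )
  if (length(val_lines) == 0) {
    stop_data("no validation end-product lines first observed in ", test_year)
  }
  train_ep <- blues_ep[blues_ep$line_id %in% tr_lines, , drop = FALSE]
  train_nir <- if (mode == "multi" && !is.null(blues_nir)) {
    blues_nir[blues_nir$line_id %in% tr_lines, , drop = FALSE]
  } else {
    NULL
  }
  truth_ep <- blues_ep[blues_ep$line_id %in% val_lines, , drop = FALSE]
  if (any(truth_ep$line_id %in% train_ep$line_id)) {
    stop("internal consistency failure: validation line in forward training")
  }
  list(train_ep = train_ep, train_nir = train_nir, truth_ep = truth_ep,
       val_lines = val_lines)
}

#' Year-wise forward prediction accuracy
#'
#' Emulates the breeder's situation: for each test year, the model is
#' trained on all lines first observed in the preceding years and predicts
#' the end-product GEBVs of lines first observed in the test year; accuracy
#' is the Pearson correlation with their held-out BLUEs. In `"multi"` mode
#' the training set additionally carries all NIR-predicted BLUEs of the
#' training-year lines in a bivariate model.
#'
#' @param blues_ep,blues_nir BLUE tables.
#' @param grm conditioned GRM.
#' @param line_years data.frame from [line_first_year()].
#' @param test_years vector of test year labels, each predicted from all
#'   earlier observed years.
#' @param mode `"multi"` (bivariate with NIR) or `"single"`.
#' @param control a [greml_control()].
#' @return `accuracy_report` with per-year accuracies and their mean.
#' @export
run_forward <- function(blues_ep, blues_nir = NULL, grm, line_years,
                        test_years, mode = c("multi", "single"),
                        control = greml_control()) {
  mode <- match.arg(mode)
  all_years <- sort(unique(line_years$first_year))
  rows <- list()
  for (ty in as.character(test_years)) {
    train_years <- all_years[all_years < ty]
    if (length(train_years) < 2) {
      stop_config("need at least 2 training years before test year ", ty)
    }
    sets <- forward_split(blues_ep, blues_nir, line_years,
                          train_years, ty, mode)
    res <- tryCatch({
      fit <- if (mode == "single" || is.null(sets$train_nir) ||
                 nrow(sets$train_nir) == 0) {
        fit_single_trait(sets$train_ep, grm, control)
      } else {
        fit_bivariate(sets$train_ep, sets$train_nir, grm, control)
      }
      gebv <- predict_gebv(fit, sets$truth_ep$line_id, trait = "ep")
      list(r = stats::cor(gebv, sets$truth_ep$blue), converged = TRUE)
    }, error = function(e) list(r = NA_real_, converged = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      test_year = ty, n_train = nrow(sets$train_ep),
      n_val = length(sets$val_lines), r = res$r, converged = res$converged
    )
  }
  years <- do.call(rbind, rows)
  structure(list(folds = years,
                 summary = data.frame(
                   mode = mode,
                   mean = mean(years$r[years$converged], na.rm = TRUE),
                   sd = stats::sd(years$r[years$converged]),
                   n_years = nrow(years), n_failed = sum(!years$converged)
                 ),
                 type = "forward"),
            class = "accuracy_report")
}
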