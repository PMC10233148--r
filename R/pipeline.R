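#' Validated run configuration
#'
#' A run is configured either from real input files (`genotypes`,
#' `phenotypes`) or from a `simulation` block (arguments to [sim_config()])
#' — exactly one of the two. The remaining keys select traits and stages:
#' `trait_ep`, `trait_nir`, `min_maf`, `ridge`, `greml` (list passed to
#' [greml_control()]), `cv` (list: `k`, `repeats`, `scenarios`), `forward`
#' (list: `test_years`, `mode`), and `seed`. Stages `cv` and `forward` run
#' only when their block is present.
#'
#' @param config a named list, or path to a YAML file holding one.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML file path")
  has_real <- !is.null(config$genotypes) || !is.null(config$phenotypes)
  has_sim <- !is.null(config$simulation)
  if (has_real && has_sim) {
    stop_config("config must name either real input files or a simulation block, not both")
  }
  if (!has_real && !has_sim) {
    stop_config("config names neither input files nor a simulation block")
  }
  if (has_real) {
    for (f in c(config$genotypes, config$phenotypes)) {
      if (!file.exists(f)) stop_config("input file does not exist: ", f)
    }
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$trait_ep <- config$trait_ep %||% "EP"
  config$trait_nir <- config$trait_nir %||% "NIR"
  config$min_maf <- config$min_maf %||% 0
  config$ridge <- config$ridge %||% 1e-6
  structure(config, class = "run_config")
}

#' Consistency diagnostics for a configured run
#'
#' Checks id consistency between genotype and phenotype inputs, duplicate
#' line ids, parseability of year labels and presence of the configured
#' trait labels. Never mutates data; returns the findings as a structured
#' table (empty when everything is clean).
#'
#' @param config a [run_config()].
#' @return data.frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`.
#' @export
validate_inputs <- function(config) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  diag <- data.frame(level = character(0), message = character(0))
  note <- function(level, msg) {
    rbind(diag, data.frame(level = level, message = msg))
  }
  if (!is.null(config$simulation)) {
    ok <- tryCatch({
      do.call(sim_config, config$simulation)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) diag <- note("error", paste("simulation block invalid:", ok))
    return(diag)
  }
  geno <- tryCatch(read_dosages(config$genotypes), error = function(e) e)
  if (inherits(geno, "error")) {
    return(note("error", paste("genotype file unreadable:", conditionMessage(geno))))
  }
  pheno <- tryCatch(read_phenotypes(config$phenotypes), error = function(e) e)
  if (inherits(pheno, "error")) {
    return(note("error", paste("phenotype file unreadable:", conditionMessage(pheno))))
  }
  if (anyDuplicated(rownames(geno))) {
    diag <- note("error", "duplicate line ids in genotype matrix")
  }
  orphans <- setdiff(unique(pheno$line_id), rownames(geno))
  if (length(orphans) > 0) {
    diag <- note("warning", paste("phenotyped lines absent from genotypes:",
                                  paste(utils::head(orphans, 10), collapse = ", ")))
  }
  if (any(is.na(suppressWarnings(as.integer(pheno$year))))) {
    diag <- note("warning", "some year labels are not integers")
  }
  for (tr in c(config$trait_ep, config$trait_nir)) {
    if (!tr %in% pheno$trait) {
      diag <- note("error", paste0("trait '", tr, "' absent from phenotype records"))
    }
  }
  diag
}

#' Run the full analysis pipeline
#'
#' Executes, as configured: simulate (or load) -> outlier edit -> per-trait
#' BLUEs -> GRM (+ conditioning, PCA) -> single-trait and bivariate GREML
#' -> cross-validation scenarios -> forward prediction, writing each
#' stage's outputs plus a JSON manifest (settings echo, seed, package
#' version, per-stage file paths) into `out_dir`, so any run can be
#' reproduced from the manifest alone. A stage failure is recorded in the
#' manifest together with the error and stops later stages.
#'
#' @param config a [run_config()] (or list / YAML path coercible to one).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("nirblup")),
    seed = config$seed,
    settings = unclass(config),
    outputs = list(),
    status = "running"
  )
  path <- function(name) file.path(out_dir, name)
  save_manifest <- function() {
    jsonlite::write_json(manifest, path("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  fail <- function(stage, e) {
    manifest$status <<- paste0("failed at stage '", stage, "': ",
                               conditionMessage(e))
    save_manifest()
    stop(e)
  }

  ## stage: inputs
  tryCatch({
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% config$seed
      scfg <- do.call(sim_config, sim_args)
      geno <- simulate_genotypes(scfg)
      sim <- simulate_phenotypes(geno, scfg)
      pheno <- apply_missingness(sim$phenotypes, scfg)
      write_dosages_raw(geno, path("genotypes.raw"))
      write_phenotypes(pheno, path("phenotypes.csv"))
      utils::write.csv(sim$truth$true_bv, path("truth_breeding_values.csv"),
                       row.names = FALSE, quote = FALSE)
      manifest$outputs$genotypes <- "genotypes.raw"
      manifest$outputs$phenotypes <- "phenotypes.csv"
      manifest$outputs$truth <- "truth_breeding_values.csv"
      config$trait_ep <- scfg$trait_ep
      config$trait_nir <- scfg$trait_nir
    } else {
      geno <- read_dosages(config$genotypes)
      pheno <- read_phenotypes(config$phenotypes)
    }
  }, error = function(e) fail("inputs", e))

  ## stage: phenotype adjustment
  tryCatch({
    edited <- edit_outliers(pheno)
    pheno <- edited$table
    blues_ep <- fit_blues(pheno, config$trait_ep)
    blues_nir <- fit_blues(pheno, config$trait_nir)
    write_blues(blues_ep, path("blues_ep.csv"))
    write_blues(blues_nir, path("blues_nir.csv"))
    manifest$outputs$blues_ep <- "blues_ep.csv"
    manifest$outputs$blues_nir <- "blues_nir.csv"
    manifest$n_outliers_removed <- nrow(edited$removed)
  }, error = function(e) fail("adjust", e))

  ## stage: GRM
  tryCatch({
    grm <- grm_condition(build_grm(geno, min_maf = config$min_maf),
                         ridge = config$ridge)
    write_grm(grm, path("grm.tsv"))
    pca <- pca_grm(grm, n_components = 2)
    utils::write.csv(
      data.frame(line_id = rownames(pca$scores), pca$scores),
      path("grm_pca_scores.csv"), row.names = FALSE, quote = FALSE)
    manifest$outputs$grm <- "grm.tsv"
    manifest$outputs$pca <- "grm_pca_scores.csv"
    manifest$pca_var_explained <- pca$var_explained
  }, error = function(e) fail("grm", e))

  ## stage: GREML fits
  ctrl <- do.call(greml_control, config$greml %||% list())
  tryCatch({
    fit1 <- fit_single_trait(blues_ep, grm, ctrl)
    fit2 <- fit_bivariate(blues_ep, blues_nir, grm, ctrl)
    comp <- list(
      single = list(sigma2_g = fit1$sigma2_g, sigma2_e = fit1$sigma2_e,
                    h2 = fit1$h2, loglik = fit1$loglik,
                    n_iter = fit1$n_iter),
      bivariate = list(G0 = fit2$G0, R0 = fit2$R0, r_g = fit2$r_g,
                       r_p = fit2$r_p, h2 = as.list(fit2$h2),
                       loglik = fit2$loglik, n_iter = fit2$n_iter)
    )
    jsonlite::write_json(comp, path("variance_components.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    gebv <- rbind(
      data.frame(line_id = names(fit2$gebv_ep), trait = config$trait_ep,
                 gebv = unname(fit2$gebv_ep)),
      data.frame(line_id = names(fit2$gebv_nir), trait = config$trait_nir,
                 gebv = unname(fit2$gebv_nir))
    )
    utils::write.csv(gebv, path("gebv.csv"), row.names = FALSE, quote = FALSE)
    manifest$outputs$variance_components <- "variance_components.json"
    manifest$outputs$gebv <- "gebv.csv"
  }, error = function(e) fail("fit", e))

  ## stage: cross-validation
  if (!is.null(config$cv)) {
    tryCatch({
      plan <- make_folds(blues_ep$line_id,
                         k = config$cv$k %||% 5,
                         repeats = config$cv$repeats %||% 10,
                         seed = config$seed)
      report <- run_cv(blues_ep, blues_nir, grm, plan,
                       scenarios = config$cv$scenarios %||%
                         c("S0", "S1", "S2", "S3"),
                       control = ctrl)
      utils::write.csv(report$folds, path("cv_accuracy.csv"),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(report$summary, path("cv_summary.json"),
                           digits = NA, force = TRUE)
      manifest$outputs$cv_accuracy <- "cv_accuracy.csv"
      manifest$outputs$cv_summary <- "cv_summary.json"
    }, error = function(e) fail("cv", e))
  }

  ## stage: forward prediction
  if (!is.null(config$forward)) {
    tryCatch({
      ly <- line_first_year(pheno)
      report <- run_forward(blues_ep, blues_nir, grm, ly,
                            test_years = config$forward$test_years,
                            mode = config$forward$mode %||% "multi",
                            control = ctrl)
      utils::write.csv(report$folds, path("forward_accuracy.csv"),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(report$summary, path("forward_summary.json"),
                           digits = NA, force = TRUE)
      manifest$outputs$forward_accuracy <- "forward_accuracy.csv"
      manifest$outputs$forward_summary <- "forward_summary.json"
    }, error = function(e) fail("forward", e))
  }

  manifest$status <- "complete"
  save_manifest()
  invisible(manifest)
}
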