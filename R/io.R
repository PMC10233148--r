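#' Read and write phenotype, genotype and BLUE tables
#'
#' The phenotype dialect is a CSV with columns `line_id`, `year`,
#' `location`, `nursery`, `trait`, `value` (an optional `record_id` column
#' is preserved). Genotypes are accepted either as a PLINK `.raw`-style
#' dosage table (header starting `FID IID PAT MAT SEX PHENOTYPE`, one
#' column per marker, whitespace-separated) or as a plain delimited matrix
#' with line ids in the first column and marker ids in the header.
#'
#' @param path file path.
#' @name table_io
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("line_id", "year", "location", "nursery", "trait", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_data("phenotype file lacks columns: ", paste(missing, collapse = ", "))
  }
  df$year <- as.character(df$year)
  if (any(!is.finite(df$value))) stop_data("non-finite phenotype values")
  df
}

#' @param table data.frame in the corresponding dialect.
#' @rdname table_io
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_dosages <- function(path) {
  header <- strsplit(readLines(path, n = 1), "[,\t ]+")[[1]]
  if (identical(toupper(header[1:2]), c("FID", "IID"))) {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE)
    ids <- as.character(df$IID)
    X <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            sep = if (grepl(",", readLines(path, n = 1))) "," else "\t")
    ids <- as.character(df[[1]])
    X <- as.matrix(df[, -1, drop = FALSE])
  }
  if (anyDuplicated(ids)) stop_data("duplicate line ids in genotype file")
  storage.mode(X) <- "double"
  bad <- !(X %in% c(0, 1, 2) | is.na(X))
  if (any(bad)) stop_data("dosage values outside {0, 1, 2, NA}")
  rownames(X) <- ids
  X
}

#' @param genotypes dosage matrix with line ids as rownames.
#' @rdname table_io
#' @export
write_dosages_raw <- function(genotypes, path) {
  df <- data.frame(FID = rownames(genotypes), IID = rownames(genotypes),
                   PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9,
                   genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param blues BLUE table (`line_id`, `trait`, `blue`, `se`, `n_records`).
#' @rdname table_io
#' @export
write_blues <- function(blues, path) {
  utils::write.csv(blues, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_blues <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("line_id", "blue") %in% names(df))) {
    stop_data("BLUE file needs at least columns line_id and blue")
  }
  df
}

#' Published trait summaries bundled with the package
#'
#' Variance components, heritabilities and end-product/NIR correlations as
#' published for six wheat end-product quality traits in the motivating
#' commercial breeding program, together with the per-year counts of lines
#' with laboratory-assayed and NIR-predicted records. Used for worked
#' examples and for configuring the synthetic generator to a realistic
#' unbalanced design.
#'
#' @return list of data.frames: `variance_components` (trait, sigma2_g,
#'   sigma2_e, H2, h2_snp), `correlations` (trait, r_g, r_g_se, r_p,
#'   r_p_se), and `line_counts` (trait, year, n_ep, n_nir).
#' @export
published_trait_summaries <- function() {
  dir <- system.file("extdata", package = "nirblup")
  list(
    variance_components = utils::read.csv(
      file.path(dir, "quality_trait_variance_components.csv"),
      stringsAsFactors = FALSE),
    correlations = utils::read.csv(
      file.path(dir, "quality_trait_correlations.csv"),
      stringsAsFactors = FALSE),
    line_counts = utils::read.csv(
      file.path(dir, "line_counts_by_year.csv"),
      stringsAsFactors = FALSE)
  )
}
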