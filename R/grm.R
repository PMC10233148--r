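#' Per-marker alternate-allele frequencies
#'
#' Frequency of marker j is the sum of non-missing dosages divided by twice
#' the number of non-missing calls.
#'
#' @param genotypes dosage matrix (lines x markers, values 0/1/2 or `NA`).
#' @return numeric vector of frequencies in `[0, 1]`, named by marker.
#' @export
compute_allele_freq <- function(genotypes) {
  n_obs <- colSums(!is.na(genotypes))
  if (any(n_obs == 0)) {
    bad <- colnames(genotypes)[n_obs == 0] %||% which(n_obs == 0)
    stop_data("markers with all calls missing: ",
              paste(utils::head(bad, 10), collapse = ", "))
  }
  colSums(genotypes, na.rm = TRUE) / (2 * n_obs)
}

#' Build the VanRaden genomic relationship matrix
#'
#' Centres dosages as `W = M - 2p` (method 1: observed-sample frequencies),
#' replaces missing dosages by their marker mean (zero after centring), and
#' scales by twice the total heterozygosity:
#' \deqn{G = W W^\top / \left(2 \sum_j p_j (1 - p_j)\right).}
#' Markers with minor-allele frequency strictly below `min_maf` are dropped
#' before centring; the default `min_maf = 0` keeps all polymorphic markers.
#'
#' @param genotypes dosage matrix (lines x markers).
#' @param freq optional frequency vector aligned to the markers; computed
#'   from the sample when `NULL`.
#' @param min_maf minor-allele-frequency threshold for dropping markers.
#' @return an object of class `nb_grm`: list with `values` (symmetric n x n
#'   matrix, line ids as dimnames), `line_ids`, `n_markers` used, and
#'   `ridge_applied` (0 until [grm_condition()] is applied).
#' @seealso [grm_condition()], [pca_grm()]
#' @export
build_grm <- function(genotypes, freq = NULL, min_maf = 0) {
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- sprintf("L%04d", seq_len(nrow(genotypes)))
  }
  if (anyDuplicated(rownames(genotypes))) {
    stop_data("duplicate line ids in genotype matrix")
  }
  if (is.null(freq)) freq <- compute_allele_freq(genotypes)
  if (length(freq) != ncol(genotypes)) {
    stop_data("frequency vector not aligned to markers")
  }
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= min_maf
  denom <- 2 * sum(freq[keep] * (1 - freq[keep]))
  if (denom <= 0) {
    stop_compute("all retained markers are monomorphic; GRM denominator is zero")
  }
  W <- sweep(genotypes[, keep, drop = FALSE], 2, 2 * freq[keep])
  W[is.na(W)] <- 0
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  structure(list(values = G, line_ids = rownames(genotypes),
                 n_markers = sum(keep), ridge_applied = 0),
            class = "nb_grm")
}

#' @export
as.matrix.nb_grm <- function(x, ...) x$values

#' @export
print.nb_grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d lines, %d markers, ridge %g\n",
              length(x$line_ids), x$n_markers %||% NA_integer_,
              x$ridge_applied))
  cat(sprintf("  mean diagonal %.3f\n", mean(diag(x$values))))
  invisible(x)
}

#' Condition a GRM for invertibility
#'
#' REML needs an invertible relationship matrix; a GRM built from fewer
#' markers than lines (or containing duplicated lines) is rank deficient.
#' If the smallest eigenvalue is below `1e-8`, a ridge of at least `ridge`
#' (raised if necessary so the smallest eigenvalue reaches `1e-8`) is added
#' to the diagonal and recorded in `ridge_applied`. Off-diagonal entries are
#' never touched.
#'
#' @param grm an `nb_grm`.
#' @param ridge minimum ridge to add when conditioning triggers (>= 0).
#' @return the conditioned `nb_grm`.
#' @export
grm_condition <- function(grm, ridge = 1e-6) {
  stopifnot(inherits(grm, "nb_grm"), ridge >= 0)
  ev_min <- min(eigen(grm$values, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= 1e-8) return(grm)
  add <- max(ridge, 1e-8 - ev_min)
  grm$values <- grm$values + diag(add, nrow(grm$values))
  grm$ridge_applied <- grm$ridge_applied + add
  grm
}

#' Principal component analysis of a GRM
#'
#' Eigen-decomposes the relationship matrix; component scores are
#' eigenvectors scaled by the square root of their eigenvalues, and the
#' variance explained by each component is its eigenvalue divided by the
#' trace. Used to inspect population structure among lines.
#'
#' @param grm an `nb_grm`.
#' @param n_components number of leading components to return.
#' @return list with `scores` (lines x components), `var_explained`
#'   (fractions, non-increasing) and `eigenvalues`.
#' @export
pca_grm <- function(grm, n_components = 2) {
  stopifnot(inherits(grm, "nb_grm"))
  G <- grm$values
  if (any(!is.finite(G))) stop_compute("GRM contains non-finite entries")
  if (n_components > nrow(G)) {
    stop_config("n_components exceeds the number of lines")
  }
  e <- eigen(G, symmetric = TRUE)
  idx <- seq_len(n_components)
  scores <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[idx], 0)), n_components)
  dimnames(scores) <- list(grm$line_ids, paste0("PC", idx))
  list(scores = scores,
       var_explained = e$values[idx] / sum(diag(G)),
       eigenvalues = e$values)
}

#' Write / read a GRM as plain text
#'
#' `write_grm` writes the square matrix as TSV with a header row of line
#' ids (and a leading id column); `write_grm_sparse` writes the
#' lower-triangle 3-column `(i, j, value)` form with ids. `read_grm` reads
#' the square TSV form back into an `nb_grm`.
#'
#' @param grm an `nb_grm`.
#' @param path output/input file path.
#' @name grm_io
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "nb_grm"))
  df <- data.frame(line_id = grm$line_ids, grm$values, check.names = FALSE)
  colnames(df) <- c("line_id", grm$line_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grm_io
#' @export
write_grm_sparse <- function(grm, path) {
  stopifnot(inherits(grm, "nb_grm"))
  idx <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = grm$line_ids[idx[, 1]], j = grm$line_ids[idx[, 2]],
                   value = grm$values[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname grm_io
#' @export
read_grm <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  G <- as.matrix(df[, -1, drop = FALSE])
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, line_ids = ids, n_markers = NA_integer_,
                 ridge_applied = 0),
            class = "nb_grm")
}
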