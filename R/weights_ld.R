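# Expression-weight features, locus LD matrices, and feature alignment.

#' Construct a gene-tissue expression-weight feature
#'
#' A feature is one (gene, expression panel) pair with per-SNP cis expression
#' weights `w`. One gene can yield several features when it is present in
#' several panels; features are the unit tested by the TWAS scan.
#'
#' @param gene gene symbol.
#' @param panel expression-panel label (e.g. `"NTR"`, `"YFS"`, `"METSIM"`).
#' @param snp_ids character vector of SNP ids, unique, same length as `w`.
#' @param w numeric weight vector; at least one entry must be nonzero.
#' @return an object of class `feature_weights`.
#' @export
feature_weights <- function(gene, panel, snp_ids, w) {
  w <- as.numeric(w)
  assert_that(length(snp_ids) == length(w),
              "snp_ids and w must have the same length")
  assert_that(!anyDuplicated(snp_ids), "snp_ids must be unique within a feature")
  assert_that(all(is.finite(w)), "weights must be finite")
  assert_that(any(w != 0),
              sprintf("feature %s/%s has all-zero weights", gene, panel))
  structure(list(gene = as.character(gene), panel = as.character(panel),
                 snp_ids = as.character(snp_ids), w = w),
            class = "feature_weights")
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("<feature_weights> %s [%s]: %d SNPs, %d nonzero\n",
              x$gene, x$panel, length(x$w), sum(x$w != 0)))
  invisible(x)
}

#' Load expression weights from a long-format file
#'
#' Reads a tab-delimited file with header `GENE`, `PANEL`, `SNP`, `WEIGHT`
#' (one row per SNP weight) and returns a list of [feature_weights()]
#' objects, one per (gene, panel) pair. Features whose weights are all zero
#' are rejected with an error naming the feature.
#'
#' @param path path to the weights file.
#' @return named list of `feature_weights` (names `"gene.panel"`).
#' @export
load_weights <- function(path) {
  assert_that(file.exists(path), sprintf("weights file not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("GENE", "PANEL", "SNP", "WEIGHT")
  missing_cols <- setdiff(needed, names(raw))
  assert_that(length(missing_cols) == 0,
              sprintf("weights file missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  key <- paste(raw$GENE, raw$PANEL, sep = ".")
  split_rows <- split(seq_len(nrow(raw)), factor(key, levels = unique(key)))
  feats <- lapply(split_rows, function(i) {
    feature_weights(raw$GENE[i[1]], raw$PANEL[i[1]],
                    raw$SNP[i], as.numeric(raw$WEIGHT[i]))
  })
  feats
}

#' Construct a locus LD (SNP-correlation) matrix
#'
#' @param D square numeric matrix of SNP correlations, symmetric with unit
#'   diagonal (both checked to 1e-8).
#' @param snp_ids SNP ids in the matrix order; defaults to `rownames(D)`.
#' @return an `ld_matrix`: the matrix with SNP ids as dimnames.
#' @export
ld_matrix <- function(D, snp_ids = rownames(D)) {
  D <- as.matrix(D)
  assert_that(nrow(D) == ncol(D), "LD matrix must be square")
  assert_that(!is.null(snp_ids) && length(snp_ids) == nrow(D),
              "snp_ids must label every row of D")
  assert_that(max(abs(D - t(D))) <= 1e-8, "LD matrix must be symmetric (tol 1e-8)")
  assert_that(max(abs(diag(D) - 1)) <= 1e-8,
              "LD matrix diagonal must be 1 (tol 1e-8)")
  dimnames(D) <- list(snp_ids, snp_ids)
  class(D) <- c("ld_matrix", class(D))
  D
}

#' Read an LD matrix from a text file
#'
#' Accepts either a square matrix file whose header row and first column are
#' SNP ids, or a dense whitespace-delimited matrix plus a sidecar file with
#' one SNP id per line.
#'
#' @param path matrix file.
#' @param snp_file optional sidecar SNP-id list for headerless matrices.
#' @return an [ld_matrix()].
#' @export
read_ld_matrix <- function(path, snp_file = NULL) {
  assert_that(file.exists(path), sprintf("LD file not found: %s", path))
  if (is.null(snp_file)) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    ld_matrix(as.matrix(tab), snp_ids = rownames(tab))
  } else {
    snps <- readLines(snp_file)
    snps <- snps[nzchar(snps)]
    m <- as.matrix(utils::read.table(path, header = FALSE))
    ld_matrix(unname(m), snp_ids = snps)
  }
}

#' Clip an LD matrix to the positive semidefinite cone
#'
#' Sampling noise (or subsetting) can leave a correlation matrix with small
#' negative eigenvalues, which would make the TWAS variance `w'Dw` negative.
#' Eigenvalues are clipped below at `eps`, the matrix is reassembled, and the
#' diagonal rescaled back to 1 (via `cov2cor`) so the result is again a
#' correlation matrix.
#'
#' @param D square symmetric matrix.
#' @param eps eigenvalue floor, default `1e-8`; a numerical floor only.
#' @return symmetric PSD matrix with unit diagonal, same dimnames as `D`.
#' @export
regularize_psd <- function(D, eps = 1e-8) {
  D <- as.matrix(D)
  assert_that(nrow(D) == ncol(D), "matrix must be square")
  assert_that(max(abs(D - t(D))) <= 1e-6, "matrix must be symmetric")
  assert_that(eps >= 0, "eps must be >= 0")
  e <- eigen(D, symmetric = TRUE)
  if (min(e$values) >= eps) return(D)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  d <- diag(out)
  if (any(d <= 0)) stop("degenerate matrix: zero diagonal after PSD projection")
  out <- stats::cov2cor(out)
  dimnames(out) <- dimnames(D)
  out
}

#' Align a feature's weights, GWAS z-scores, and LD matrix
#'
#' Restricts the weight vector, z-scores and LD matrix to the SNPs present
#' in all three inputs, in the LD matrix's order (the single source of
#' truth for SNP order). Features whose overlap with the weight SNPs falls
#' below `min_overlap_fraction` are skipped so near-empty weight vectors do
#' not produce spurious statistics.
#'
#' @param fw a [feature_weights()].
#' @param ss a `gwas_sumstats` (harmonized to the same panel as `ld`).
#' @param ld an [ld_matrix()] covering the locus.
#' @param min_overlap_fraction minimum `n_overlap / length(fw$snp_ids)` to
#'   proceed, default `0.5`.
#' @return an `aligned_feature` (list with `gene`, `panel`, `w`, `z`, `D`,
#'   `snp_ids`, `n_overlap`, `overlap_fraction`), or `NULL` with attribute
#'   `"skip_reason"` when the overlap is insufficient or the restricted
#'   weights are all zero.
#' @export
align_feature <- function(fw, ss, ld, min_overlap_fraction = 0.5) {
  stopifnot(inherits(fw, "feature_weights"))
  common <- intersect(intersect(fw$snp_ids, ss$snp_id), rownames(ld))
  # canonical order: order of appearance in the LD matrix
  common <- rownames(ld)[rownames(ld) %in% common]
  n_overlap <- length(common)
  frac <- n_overlap / length(fw$snp_ids)
  if (n_overlap < 1 || frac < min_overlap_fraction) {
    return(structure(list(), class = "skipped_feature",
                     skip_reason = sprintf(
                       "%s/%s: overlap %d/%d (%.2f) below min_overlap_fraction %.2f",
                       fw$gene, fw$panel, n_overlap, length(fw$snp_ids),
                       frac, min_overlap_fraction)))
  }
  w <- fw$w[match(common, fw$snp_ids)]
  if (all(w == 0)) {
    return(structure(list(), class = "skipped_feature",
                     skip_reason = sprintf("%s/%s: all retained weights zero",
                                           fw$gene, fw$panel)))
  }
  z <- ss$z[match(common, ss$snp_id)]
  D <- unclass(ld)[common, common, drop = FALSE]
  structure(list(gene = fw$gene, panel = fw$panel, snp_ids = common,
                 w = w, z = z, D = D,
                 n_overlap = n_overlap, overlap_fraction = frac),
            class = "aligned_feature")
}

#' @keywords internal
#' @noRd
is_skipped <- function(x) inherits(x, "skipped_feature")
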