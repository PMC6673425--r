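# The TWAS association statistic, its p-value, the genomic inflation
# factor, and the panel-wide scan.

#' LD-adjusted weighted z-score TWAS statistic
#'
#' Computes the summary-based TWAS association statistic
#' \deqn{Z_{TWAS} = w'Z / \sqrt{w'Dw}}
#' for one gene-tissue feature: the linear combination of GWAS z-scores `z`
#' under expression weights `w`, standardized by the variance `w'Dw` implied
#' by the SNP-correlation (LD) matrix `D`. Under the null, with
#' `z ~ MVN(0, D)`, the statistic is standard normal. It is invariant under
#' positive rescaling of `w` and flips sign when `w` is negated.
#'
#' @param w numeric weight vector.
#' @param z numeric GWAS z-score vector, same length and SNP order as `w`.
#' @param D SNP-correlation matrix, symmetric PSD, same order.
#' @param tol features with `w'Dw <= tol` (default `1e-10`) are degenerate:
#'   the statistic is undefined and an error of class
#'   `"sumtwas_degenerate"` is raised so callers can report the feature as
#'   failed rather than aborting a scan.
#' @return the scalar TWAS z-score.
#' @examples
#' twas_zscore(c(0.5, 0.5), c(2, 3), matrix(c(1, .5, .5, 1), 2))
#' @export
twas_zscore <- function(w, z, D, tol = 1e-10) {
  w <- as.numeric(w); z <- as.numeric(z); D <- as.matrix(D)
  assert_that(length(w) == length(z) && length(w) == nrow(D) && nrow(D) == ncol(D),
              "w, z, and D must agree in dimension")
  assert_that(all(is.finite(w)) && all(is.finite(z)), "w and z must be finite")
  denom2 <- drop(crossprod(w, D %*% w))
  if (!is.finite(denom2) || denom2 <= tol) {
    stop(structure(class = c("sumtwas_degenerate", "error", "condition"),
                   list(message = sprintf(
                     "w'Dw = %.3g <= tolerance %.3g: TWAS statistic undefined",
                     denom2, tol), call = sys.call(-1))))
  }
  drop(crossprod(w, z)) / sqrt(denom2)
}

#' Two-sided normal p-value for a z-score
#'
#' `p = 2 * P(N(0,1) >= |z|)`, computed on the upper tail directly
#' (`pnorm(..., lower.tail = FALSE)`), which is numerically stable far into
#' the tail where `1 - pnorm(z)` would cancel to zero.
#'
#' @param z numeric vector of z-scores, all finite.
#' @return two-sided p-values in (0, 1].
#' @examples
#' z_to_p(6.2053)   # 5.46e-10
#' z_to_p(-4.8058)  # 1.54e-06
#' @export
z_to_p <- function(z) {
  assert_that(length(z) >= 1 && all(is.finite(z)), "z must be finite")
  pmin(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Genomic inflation factor
#'
#' `lambda = median(z^2) / qchisq(0.5, df = 1)`: the median observed 1-df
#' chi-square statistic over its theoretical null median (0.4549364).
#' Values above 1 indicate inflation of the test-statistic distribution.
#'
#' @param z_values numeric vector of z-scores; non-finite entries are an
#'   error, as is an empty vector.
#' @return scalar lambda.
#' @export
genomic_lambda <- function(z_values) {
  assert_that(length(z_values) >= 1, "need at least one z value")
  assert_that(all(is.finite(z_values)), "z values must be finite")
  stats::median(z_values^2) / stats::qchisq(0.5, df = 1)
}

#' Scan all gene-tissue features against a GWAS
#'
#' Runs the TWAS statistic for every feature: aligns each feature's weights
#' with the summary statistics and its locus LD matrix, computes
#' `z_twas` and its two-sided p, and (optionally) the permutation empirical
#' p. Per-feature failures (insufficient overlap, degenerate `w'Dw`) become
#' skip records; the scan never aborts. Output is deterministic given the
#' inputs and `seed`.
#'
#' @param sumstats a `gwas_sumstats`.
#' @param features list of [feature_weights()].
#' @param ld_source either a named list of [ld_matrix()] objects keyed by
#'   `"gene.panel"` or by gene, or a function `(gene, panel) -> ld_matrix`.
#' @param min_overlap_fraction passed to [align_feature()], default 0.5.
#' @param n_perm permutations per feature for the empirical p
#'   (default 0 = none; the reference analysis used 5000).
#' @param seed master seed for the permutation streams; per-feature
#'   sub-seeds are derived from (seed, gene, panel) so results do not
#'   depend on scan order.
#' @param eps PSD eigenvalue floor applied to each locus LD matrix.
#' @return data frame with columns `gene`, `panel`, `n_overlap`, `z_twas`,
#'   `p_twas` and (when `n_perm > 0`) `p_perm`; skipped features are
#'   recorded in `attr(x, "skipped")` (character vector of reasons).
#' @export
scan_panels <- function(sumstats, features, ld_source,
                        min_overlap_fraction = 0.5, n_perm = 0, seed = 1,
                        eps = 1e-8) {
  get_ld <- if (is.function(ld_source)) {
    ld_source
  } else {
    function(gene, panel) {
      ld_source[[paste(gene, panel, sep = ".")]] %||% ld_source[[gene]]
    }
  }
  rows <- vector("list", length(features))
  skipped <- character(0)
  for (i in seq_along(features)) {
    fw <- features[[i]]
    ld <- get_ld(fw$gene, fw$panel)
    if (is.null(ld)) {
      skipped <- c(skipped, sprintf("%s/%s: no LD matrix", fw$gene, fw$panel))
      next
    }
    af <- align_feature(fw, sumstats, ld, min_overlap_fraction)
    if (is_skipped(af)) {
      skipped <- c(skipped, attr(af, "skip_reason"))
      next
    }
    af$D <- regularize_psd(af$D, eps)
    zt <- tryCatch(twas_zscore(af$w, af$z, af$D),
                   sumtwas_degenerate = function(e) e)
    if (inherits(zt, "condition")) {
      skipped <- c(skipped, sprintf("%s/%s: %s", fw$gene, fw$panel,
                                    conditionMessage(zt)))
      next
    }
    row <- data.frame(gene = af$gene, panel = af$panel,
                      n_overlap = af$n_overlap,
                      z_twas = zt, p_twas = z_to_p(zt),
                      stringsAsFactors = FALSE)
    if (n_perm > 0) {
      pr <- permutation_p(af, n_perm = n_perm,
                          seed = feature_seed(seed, af$gene, af$panel))
      row$p_perm <- pr$p_empirical
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene = character(0), panel = character(0),
                      n_overlap = integer(0), z_twas = numeric(0),
                      p_twas = numeric(0), stringsAsFactors = FALSE)
    if (n_perm > 0) out$p_perm <- numeric(0)
  }
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}

#' Write a TWAS results table
#'
#' Tab-delimited with columns `GENE`, `PANEL`, `NSNPS_USED`, `ZTWAS`,
#' `P_TWAS` (and `P_PERM` when present), numeric columns in scientific
#' notation with 4+ significant digits.
#'
#' @param results data frame from [scan_panels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_twas_results <- function(results, path) {
  out <- data.frame(GENE = results$gene, PANEL = results$panel,
                    NSNPS_USED = results$n_overlap,
                    ZTWAS = sprintf("%.4e", results$z_twas),
                    P_TWAS = sprintf("%.4e", results$p_twas),
                    stringsAsFactors = FALSE)
  if (!is.null(results$p_perm)) out$P_PERM <- sprintf("%.4e", results$p_perm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
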