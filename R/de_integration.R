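# Differential-expression filter, Bonferroni bookkeeping, and the
# TWAS x expression-profiling intersection.

#' Read a differential-expression table
#'
#' Tab-delimited with header `GENE`, `FC`, `P`: gene symbol, case/control
#' fold change (ratio scale, > 0), and uncorrected p-value.
#'
#' @param path path to the table.
#' @return data frame with columns `gene`, `fold_change`, `p_uncorrected`.
#' @export
read_de_table <- function(path) {
  assert_that(file.exists(path), sprintf("DE table not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("GENE", "FC", "P"), names(raw))
  assert_that(length(missing_cols) == 0,
              sprintf("DE table missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  out <- data.frame(gene = as.character(raw$GENE),
                    fold_change = as.numeric(raw$FC),
                    p_uncorrected = as.numeric(raw$P),
                    stringsAsFactors = FALSE)
  assert_that(all(nzchar(out$gene)), "gene symbols must be non-empty")
  assert_that(all(is.finite(out$fold_change) & out$fold_change > 0),
              "fold changes must be finite and positive")
  out
}

#' Apply the differential-expression filter
#'
#' Selects genes by fold change and uncorrected p. In `symmetric` mode
#' (default) a gene passes when `max(FC, 1/FC) > fc_thresh`, i.e. both up-
#' and down-regulation count; `up_only` reads the fold-change rule
#' literally and keeps `FC > fc_thresh` only. The p rule is
#' `p < p_thresh`, strict. Duplicated symbols collapse to one.
#'
#' @param table data frame with `gene`, `fold_change`, `p_uncorrected`
#'   columns (see [read_de_table()]).
#' @param fc_thresh fold-change threshold (> 1), default 1.2.
#' @param p_thresh uncorrected-p threshold, default 0.05.
#' @param direction `"symmetric"` or `"up_only"`.
#' @return character vector of differentially expressed gene symbols.
#' @export
filter_de <- function(table, fc_thresh = 1.2, p_thresh = 0.05,
                      direction = c("symmetric", "up_only")) {
  direction <- match.arg(direction)
  assert_that(fc_thresh > 1, "fc_thresh must exceed 1")
  assert_that(p_thresh > 0 && p_thresh <= 1, "p_thresh must lie in (0, 1]")
  fc <- table$fold_change
  mag <- if (direction == "symmetric") pmax(fc, 1 / fc) else fc
  keep <- mag > fc_thresh & table$p_uncorrected < p_thresh
  unique(table$gene[keep])
}

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error rate in (0, 1], default 0.05.
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  assert_that(alpha > 0 && alpha <= 1, "alpha must lie in (0, 1]")
  assert_that(is.numeric(m) && length(m) == 1 && m >= 1,
              "m must be a positive count")
  alpha / m
}

#' Count features passing the Bonferroni threshold
#'
#' Counts z-scores whose two-sided normal p falls strictly below
#' `alpha / m`.
#'
#' @param z_values numeric z-scores.
#' @param alpha family-wise error rate, default 0.05.
#' @param m number of tests in the family.
#' @return integer count.
#' @export
count_bonferroni_hits <- function(z_values, alpha = 0.05, m) {
  if (length(z_values) == 0) return(0L)
  sum(z_to_p(z_values) < bonferroni_threshold(alpha, m))
}

#' Intersect significant TWAS features with a DE gene list
#'
#' Retains the feature rows whose gene symbol (case-insensitive exact
#' match) appears in the differentially expressed set, then collapses to
#' unique genes. The intersection happens at the feature level first —
#' one gene significant in two panels contributes two feature rows and one
#' unique gene. Rows are ordered by ascending `p_twas`, ties by symbol,
#' so the report is deterministic.
#'
#' @param sig_features data frame with at least `gene`, `panel`, `p_twas`
#'   (typically the output of [significant_features()]).
#' @param de_genes character vector of DE gene symbols
#'   (typically [filter_de()] output).
#' @return an `overlap_report`: list with `feature_rows` (retained rows),
#'   `unique_genes`, `n_features`, `n_unique`, `multi_panel_genes`
#'   (genes significant in >= 2 distinct panels), and `per_panel_counts`.
#' @export
intersect_with_de <- function(sig_features, de_genes) {
  needed <- c("gene", "panel", "p_twas")
  assert_that(all(needed %in% names(sig_features)),
              "sig_features needs columns gene, panel, p_twas")
  keep <- toupper(sig_features$gene) %in% toupper(de_genes)
  rows <- sig_features[keep, , drop = FALSE]
  ord <- order(rows$p_twas, rows$gene)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  uniq <- unique(rows$gene)
  panels_per_gene <- tapply(rows$panel, rows$gene,
                            function(p) length(unique(p)))
  multi <- names(panels_per_gene)[panels_per_gene >= 2]
  per_panel <- if (nrow(rows) > 0) {
    tab <- table(rows$panel)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    integer(0)
  }
  structure(list(feature_rows = rows,
                 unique_genes = uniq,
                 n_features = nrow(rows),
                 n_unique = length(uniq),
                 multi_panel_genes = sort(multi),
                 per_panel_counts = per_panel),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d feature rows, %d unique genes, %d multi-panel\n",
              x$n_features, x$n_unique, length(x$multi_panel_genes)))
  if (x$n_features > 0) {
    cat("per-panel counts:",
        paste(sprintf("%s=%d", names(x$per_panel_counts), x$per_panel_counts),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Format an overlap report as a wide candidate table
#'
#' One row per unique gene, one p_twas column per panel with `"/"` marking
#' panels where the gene was not significant, plus the DE p when a DE
#' table is supplied — the layout used for published candidate-gene lists.
#'
#' @param report an `overlap_report`.
#' @param de_table optional DE data frame (see [read_de_table()]) supplying
#'   the `P_mRNA` column.
#' @return data frame in wide layout.
#' @export
format_overlap_wide <- function(report, de_table = NULL) {
  rows <- report$feature_rows
  panels <- sort(unique(rows$panel))
  genes <- report$unique_genes
  out <- data.frame(GENE = genes, stringsAsFactors = FALSE)
  for (p in panels) {
    col <- rep("/", length(genes))
    sub <- rows[rows$panel == p, , drop = FALSE]
    hit <- match(sub$gene, genes)
    col[hit] <- sprintf("%.5g", sub$p_twas)
    out[[p]] <- col
  }
  if (!is.null(de_table)) {
    idx <- match(toupper(genes), toupper(de_table$gene))
    out$P_mRNA <- ifelse(is.na(idx), "/",
                         sprintf("%.4g", de_table$p_uncorrected[idx]))
  }
  out
}
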