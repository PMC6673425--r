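# End-to-end orchestration: scan -> permutation -> significance filter ->
# DE filter -> intersection -> enrichment, with per-stage outputs.

#' Pipeline configuration
#'
#' Paths and thresholds for a full run. All thresholds default to the
#' conventions of the reference analysis: transcriptome-wide p < 0.05,
#' permutation p < 0.05, Bonferroni family alpha 0.05, fold change > 1.2
#' with uncorrected p < 0.05 for differential expression, and raw
#' enrichment p < 0.05.
#'
#' @param sumstats,weights,ld_dir,de_table,gmt input paths: summary
#'   statistics TSV, long-format weights TSV, directory of `ld_<gene>.tsv`
#'   matrices, DE table TSV, and GMT annotations.
#' @param out_dir output directory for per-stage tables, default
#'   `"sumtwas_out"`.
#' @param p_twas,p_perm,bonferroni_alpha,fc,de_p,go_p thresholds.
#' @param n_perm permutations per feature, default 5000.
#' @param min_overlap_fraction minimum weight/GWAS SNP overlap, default 0.5.
#' @param direction DE filter mode, `"symmetric"` (default) or `"up_only"`.
#' @param method enrichment method, `"hypergeometric"` (default) or
#'   `"ease"`.
#' @param seed master seed for the permutation streams.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(sumstats, weights, ld_dir, de_table, gmt,
                            out_dir = "sumtwas_out",
                            p_twas = 0.05, p_perm = 0.05,
                            bonferroni_alpha = 0.05,
                            fc = 1.2, de_p = 0.05, go_p = 0.05,
                            n_perm = 5000, min_overlap_fraction = 0.5,
                            direction = c("symmetric", "up_only"),
                            method = c("hypergeometric", "ease"),
                            seed = 1) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  for (th in c(p_twas, p_perm, bonferroni_alpha, de_p, go_p)) {
    assert_that(th > 0 && th <= 1, "thresholds must lie in (0, 1]")
  }
  assert_that(fc > 1, "fold-change threshold must exceed 1")
  structure(list(sumstats = sumstats, weights = weights, ld_dir = ld_dir,
                 de_table = de_table, gmt = gmt, out_dir = out_dir,
                 p_twas = p_twas, p_perm = p_perm,
                 bonferroni_alpha = bonferroni_alpha,
                 fc = fc, de_p = de_p, go_p = go_p,
                 n_perm = n_perm,
                 min_overlap_fraction = min_overlap_fraction,
                 direction = direction, method = method, seed = seed),
            class = "pipeline_config")
}

#' Run the full integrative pipeline
#'
#' Executes every stage on file inputs (or on an in-memory `study` list as
#' produced by [generate_study()]): the TWAS scan with permutation filter,
#' the significance filter, the DE filter, the TWAS-DE intersection, and
#' gene-set enrichment of the overlap genes. Per-stage TSVs, a JSON
#' summary and a log are written under `config$out_dir`. Per-feature
#' failures are logged, never fatal; unreadable inputs abort before any
#' computation.
#'
#' @param config a [pipeline_config()].
#' @param study optional in-memory study (list with `sumstats`, `features`,
#'   `ld`, `de_table`, `go`) overriding the file inputs.
#' @return list of class `pipeline_run` with `results` (full scan),
#'   `significant`, `de_genes`, `overlap` (an `overlap_report`),
#'   `enrichment`, `lambda`, and `summary` (the machine-readable counts).
#' @export
run_pipeline <- function(config, study = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(study)) {
    for (p in c(config$sumstats, config$weights, config$de_table, config$gmt)) {
      assert_that(file.exists(p), sprintf("input not readable: %s", p))
    }
    assert_that(dir.exists(config$ld_dir),
                sprintf("LD directory not readable: %s", config$ld_dir))
    study <- list(
      sumstats = read_sumstats(config$sumstats),
      features = load_weights(config$weights),
      ld = local({
        files <- list.files(config$ld_dir, pattern = "^ld_.*\\.tsv$",
                            full.names = TRUE)
        assert_that(length(files) > 0, "no ld_*.tsv files in ld_dir")
        out <- lapply(files, read_ld_matrix)
        names(out) <- sub("^ld_(.*)\\.tsv$", "\\1", basename(files))
        out
      }),
      de_table = read_de_table(config$de_table),
      go = read_gmt(config$gmt))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("sumtwas %s", as.character(utils::packageVersion("sumtwas"))),
                 sprintf("R %s", as.character(getRversion())),
                 sprintf("seed %d, n_perm %d", config$seed, config$n_perm),
                 paste("config:", paste(sprintf("%s=%s",
                       names(config)[-(1:6)],
                       vapply(config[-(1:6)], function(x) paste(x, collapse = ","),
                              character(1))), collapse = " ")))

  results <- scan_panels(study$sumstats, study$features, study$ld,
                         min_overlap_fraction = config$min_overlap_fraction,
                         n_perm = config$n_perm, seed = config$seed)
  skipped <- attr(results, "skipped")
  lambda <- if (nrow(results) > 0) genomic_lambda(results$z_twas) else NA_real_
  write_twas_results(results, file.path(config$out_dir, "twas_results.tsv"))

  sig <- significant_features(results, config$p_twas, config$p_perm)
  write_twas_results(sig, file.path(config$out_dir, "significant_features.tsv"))

  de_genes <- filter_de(study$de_table, fc_thresh = config$fc,
                        p_thresh = config$de_p, direction = config$direction)
  writeLines(de_genes, file.path(config$out_dir, "de_genes.txt"))

  overlap <- intersect_with_de(sig, de_genes)
  utils::write.table(format_overlap_wide(overlap, study$de_table),
                     file.path(config$out_dir, "overlap_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  enr <- enrich(overlap$unique_genes, study$go, method = config$method,
                p_thresh = config$go_p)
  utils::write.table(
    data.frame(Category = enr$category, ID = enr$term_id, Name = enr$name,
               Pvalue = sprintf("%.4g", enr$p), k = enr$k, K = enr$K,
               n = enr$n, N = enr$N),
    file.path(config$out_dir, "enrichment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  n_bonf <- if (nrow(results) > 0) {
    count_bonferroni_hits(results$z_twas, config$bonferroni_alpha, nrow(results))
  } else 0L
  summary <- list(
    n_features_tested = nrow(results),
    n_features_skipped = length(skipped),
    lambda = lambda,
    n_bonferroni_hits = n_bonf,
    n_significant_features = nrow(sig),
    n_de_genes = length(de_genes),
    n_overlap_features = overlap$n_features,
    n_overlap_unique_genes = overlap$n_unique,
    n_multi_panel_genes = length(overlap$multi_panel_genes),
    n_significant_terms = sum(enr$significant))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(log_lines, sprintf("skipped features: %d", length(skipped)),
                 skipped)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  structure(list(results = results, significant = sig, de_genes = de_genes,
                 overlap = overlap, enrichment = enr, lambda = lambda,
                 summary = summary),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<pipeline_run>\n",
    "  features tested     : %d (%d skipped)\n",
    "  genomic lambda      : %.3f\n",
    "  Bonferroni hits     : %d\n",
    "  significant features: %d\n",
    "  DE genes            : %d\n",
    "  overlap             : %d features / %d unique genes (%d multi-panel)\n",
    "  significant GO terms: %d\n"),
    s$n_features_tested, s$n_features_skipped, s$lambda, s$n_bonferroni_hits,
    s$n_significant_features, s$n_de_genes, s$n_overlap_features,
    s$n_overlap_unique_genes, s$n_multi_panel_genes, s$n_significant_terms))
  invisible(x)
}

#' Top-k features by significance
#'
#' Sorts by ascending `p_twas`, ties broken alphabetically by gene symbol,
#' and returns the first `k` rows — the layout of a published top-hits
#' table.
#'
#' @param results data frame from [scan_panels()].
#' @param k number of rows, default 10; values beyond the row count return
#'   everything.
#' @return the top rows, re-ranked.
#' @export
report_top <- function(results, k = 10) {
  ord <- order(results$p_twas, results$gene)
  out <- results[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
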