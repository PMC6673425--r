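# GWAS summary-statistics input: parsing, validation, allele harmonization.

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistics file with a header and returns a
#' validated `gwas_sumstats` data frame with columns `snp_id`, `chrom`,
#' `pos`, `allele_effect`, `allele_other`, `z`. Rows with a missing or
#' non-finite z-score are dropped and counted; duplicated SNP ids keep the
#' first occurrence with a warning.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param column_map named character vector mapping internal names
#'   (`snp_id`, `chrom`, `pos`, `allele_effect`, `allele_other`, `z`) to the
#'   file's column names. Defaults to the conventional
#'   `SNP, CHR, BP, A1, A2, Z` layout; supply only the entries you need to
#'   override.
#' @return a `gwas_sumstats` data frame. The number of rows dropped for a
#'   missing/non-finite z and for duplicate ids is attached as
#'   `attr(x, "audit")`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\tCHR\tBP\tA1\tA2\tZ",
#'              "rs1\t1\t100\tA\tG\t1.5",
#'              "rs2\t1\t200\tC\tT\t-0.3"), tf)
#' ss <- read_sumstats(tf)
#' nrow(ss)
#' @export
read_sumstats <- function(path, column_map = NULL) {
  assert_that(file.exists(path), sprintf("summary-statistics file not found: %s", path))
  defaults <- c(snp_id = "SNP", chrom = "CHR", pos = "BP",
                allele_effect = "A1", allele_other = "A2", z = "Z")
  map <- defaults
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(defaults))
    assert_that(length(bad) == 0,
                sprintf("unknown column_map entries: %s", paste(bad, collapse = ", ")))
    map[names(column_map)] <- column_map
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(map), names(raw))
  assert_that(length(missing_cols) == 0,
              sprintf("summary-statistics file is missing required column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  out <- data.frame(
    snp_id = raw[[map["snp_id"]]],
    chrom = raw[[map["chrom"]]],
    pos = suppressWarnings(as.integer(raw[[map["pos"]]])),
    allele_effect = toupper(raw[[map["allele_effect"]]]),
    allele_other = toupper(raw[[map["allele_other"]]]),
    z = suppressWarnings(as.numeric(raw[[map["z"]]])),
    stringsAsFactors = FALSE
  )
  bad_z <- !is.finite(out$z)
  n_bad_z <- sum(bad_z)
  out <- out[!bad_z, , drop = FALSE]
  dup <- duplicated(out$snp_id)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warning(sprintf("%d duplicated SNP id(s); keeping first occurrence", n_dup))
    out <- out[!dup, , drop = FALSE]
  }
  assert_that(nrow(out) > 0, "no valid summary-statistics rows after filtering")
  validate_sumstats(out)
  rownames(out) <- NULL
  structure(out,
            audit = c(n_read = nrow(raw), n_dropped_z = n_bad_z, n_dropped_dup = n_dup),
            class = c("gwas_sumstats", "data.frame"))
}

#' @keywords internal
#' @noRd
validate_sumstats <- function(x) {
  assert_that(!anyDuplicated(x$snp_id), "snp_id values must be unique")
  assert_that(all(is.finite(x$z)), "z must be finite for every record")
  assert_that(all(x$allele_effect != x$allele_other),
              "allele_effect must differ from allele_other")
  invisible(x)
}

#' @keywords internal
#' @noRd
as_gwas_sumstats <- function(df) {
  validate_sumstats(df)
  class(df) <- unique(c("gwas_sumstats", class(df)))
  df
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Harmonize summary-statistic alleles against a reference panel
#'
#' Matches each SNP's effect/other allele pair against the LD reference
#' panel's pair. An exact match keeps z unchanged; swapped effect/other
#' alleles flip the sign of z (the effect is reported for the opposite
#' allele); strand-ambiguous pairs (A/T and C/G) are dropped under the
#' default policy because their orientation cannot be resolved from alleles
#' alone; SNPs absent from the panel, and irreconcilable pairs, are dropped.
#' Strand flips (both alleles complemented) are resolved for unambiguous
#' pairs.
#'
#' @param sumstats a `gwas_sumstats` data frame (see [read_sumstats()]).
#' @param panel_alleles data frame with columns `snp_id`, `allele_effect`,
#'   `allele_other` giving the panel's orientation per SNP.
#' @param drop_ambiguous drop A/T and C/G SNPs (default `TRUE`). When
#'   `FALSE`, ambiguous SNPs are kept only on an exact or swapped literal
#'   match.
#' @param flip_swapped flip the z sign when alleles are swapped relative to
#'   the panel (default `TRUE`); when `FALSE` swapped SNPs are dropped and
#'   counted as mismatched.
#' @return a harmonized `gwas_sumstats` restricted to panel SNPs, with
#'   `attr(x, "audit")` counting `matched`, `flipped`, `ambiguous_dropped`,
#'   `absent_dropped`, `mismatch_dropped`; the counts always sum to
#'   `nrow(sumstats)`.
#' @export
harmonize_alleles <- function(sumstats, panel_alleles,
                              drop_ambiguous = TRUE, flip_swapped = TRUE) {
  assert_that(all(c("snp_id", "allele_effect", "allele_other") %in% names(panel_alleles)),
              "panel_alleles needs columns snp_id, allele_effect, allele_other")
  n_in <- nrow(sumstats)
  idx <- match(sumstats$snp_id, panel_alleles$snp_id)
  absent <- is.na(idx)

  a1 <- sumstats$allele_effect
  a2 <- sumstats$allele_other
  p1 <- toupper(panel_alleles$allele_effect[idx])
  p2 <- toupper(panel_alleles$allele_other[idx])
  ambiguous <- !absent & (a1 == unname(COMPLEMENT[a2]))

  exact <- !absent & a1 == p1 & a2 == p2
  swapped <- !absent & a1 == p2 & a2 == p1
  # strand-flipped variants (panel on the other strand); ambiguous pairs are
  # indistinguishable from swaps here, so they only count when retained
  c1 <- unname(COMPLEMENT[a1])
  c2 <- unname(COMPLEMENT[a2])
  strand_exact <- !absent & !exact & !swapped & c1 == p1 & c2 == p2
  strand_swap <- !absent & !exact & !swapped & c1 == p2 & c2 == p1

  keep_same <- exact | strand_exact
  keep_flip <- swapped | strand_swap
  if (drop_ambiguous) {
    keep_same <- keep_same & !ambiguous
    keep_flip <- keep_flip & !ambiguous
  }
  if (!flip_swapped) keep_flip <- keep_flip & FALSE

  kept <- keep_same | keep_flip
  dropped_ambiguous <- ambiguous & !absent & !kept
  mismatch <- !absent & !kept & !dropped_ambiguous

  out <- sumstats[kept, , drop = FALSE]
  flip_kept <- keep_flip[kept]
  out$z[flip_kept] <- -out$z[flip_kept]
  # harmonized records adopt the panel orientation
  out$allele_effect <- p1[kept]
  out$allele_other <- p2[kept]
  rownames(out) <- NULL

  audit <- c(matched = sum(keep_same),
             flipped = sum(keep_flip),
             ambiguous_dropped = sum(dropped_ambiguous),
             absent_dropped = sum(absent),
             mismatch_dropped = sum(mismatch))
  stopifnot(sum(audit) == n_in)
  structure(as_gwas_sumstats(out), audit = audit)
}
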