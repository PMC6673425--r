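# Shared fixtures and independent oracles for the test suite.

# write a small tab-delimited sumstats file and return its path
write_sumstats_file <- function(rows, path = tempfile(fileext = ".tsv"),
                                header = "SNP\tCHR\tBP\tA1\tA2\tZ") {
  writeLines(c(header, rows), path)
  path
}

# minimal aligned-feature list for direct statistic calls
make_af <- function(w, z, D, gene = "G1", panel = "P1") {
  list(gene = gene, panel = panel, w = w, z = z, D = as.matrix(D),
       snp_ids = paste0("snp", seq_along(w)),
       n_overlap = length(w), overlap_fraction = 1)
}

# independent dense evaluation of the TWAS statistic (no shared code path)
oracle_twas <- function(w, z, D) {
  num <- sum(w * z)
  den <- 0
  for (i in seq_along(w)) for (j in seq_along(w)) den <- den + w[i] * D[i, j] * w[j]
  num / sqrt(den)
}

# exhaustive two-sided extremeness probability over all weight arrangements,
# with the same tie tolerance the permutation engine uses
oracle_perm_exact <- function(w, z, D, z_obs) {
  mean(vapply(all_permutations(w), function(wp) {
    abs(oracle_twas(wp, z, D)) >= abs(z_obs) * (1 - 1e-9) - 1e-12
  }, logical(1)))
}

# exhaustive permutation distribution of |z_twas| for small weight vectors
all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# brute-force hypergeometric upper tail: enumerate every n-subset of an
# N-gene universe containing K term genes, count overlaps >= k
oracle_hypergeom <- function(k, K, n, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # genes 1..K are the term genes
  mean(hits >= k)
}
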