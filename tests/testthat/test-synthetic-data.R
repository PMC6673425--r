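test_that("make_ld builds the AR(1) correlation with PSD spectrum", {
  expect_equal(unname(unclass(make_ld(4, 0))), diag(4))
  D <- unclass(make_ld(3, 0.5))
  expect_equal(unname(D[1, ]), c(1, 0.5, 0.25))
  expect_equal(D, t(D))
  for (rho in c(-0.9, -0.3, 0.2, 0.8, 0.99)) {
    e <- eigen(unclass(make_ld(15, rho)), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(e), 0)
  }
  expect_error(make_ld(3, 1), "< 1")
})

test_that("simulate_weights respects the sparsity ceiling and is seed-deterministic", {
  w_full <- simulate_weights(10, 1, seed = 1)
  expect_equal(sum(w_full != 0), 10)
  w_one <- simulate_weights(10, 1 / 10, seed = 2)
  expect_equal(sum(w_one != 0), 1)
  expect_equal(sum(simulate_weights(10, 0.25, seed = 3) != 0), ceiling(0.25 * 10))
  expect_identical(simulate_weights(8, 0.5, seed = 4), simulate_weights(8, 0.5, seed = 4))
})

test_that("simulate_gwas_z has the null moments and correlation structure of MVN(0, D)", {
  set.seed(6)
  Z0 <- simulate_gwas_z(make_ld(5, 0), rep(0, 5), gwas_n = 1e5, n_draws = 10000)
  expect_true(all(abs(colMeans(Z0)) < 0.05))
  expect_true(all(abs(apply(Z0, 2, var) - 1) < 0.05))

  D <- make_ld(4, 0.6)
  Z <- simulate_gwas_z(D, rep(0, 4), gwas_n = 1e5, n_draws = 10000)
  expect_lt(max(abs(cor(Z) - unclass(D))), 0.05)

  expect_identical(simulate_gwas_z(D, rep(0, 4), 100, seed = 11),
                   simulate_gwas_z(D, rep(0, 4), 100, seed = 11))
})

test_that("plant_causal yields the closed-form expected TWAS z-score", {
  # single-SNP feature: E[z_twas] = sqrt(n) * effect exactly
  ld1 <- make_ld(1, 0, snp_ids = "s1")
  fw1 <- feature_weights("G", "P", "s1", 2.5)
  beta1 <- plant_causal(fw1, ld1, effect = 0.01)
  mu <- sqrt(1e4) * drop(unclass(ld1) %*% beta1)  # E[Z] at the locus
  expect_equal(twas_zscore(fw1$w, mu, unclass(ld1)), sqrt(1e4) * 0.01,
               tolerance = 1e-12)
  expect_equal(plant_causal(fw1, ld1, effect = 0), 0)

  # general case: Monte-Carlo mean within 3 SE of sqrt(n) * effect
  set.seed(17)
  m <- 8
  ld <- make_ld(m, 0.6, snp_ids = paste0("s", 1:m))
  fw <- feature_weights("G", "P", paste0("s", 1:m), simulate_weights(m, 0.5))
  beta <- plant_causal(fw, ld, effect = 0.02)
  n_gwas <- 1e4
  B <- 5000
  Z <- simulate_gwas_z(ld, beta, n_gwas, n_draws = B)
  stats <- apply(Z, 1, function(z) twas_zscore(fw$w, z, unclass(ld)))
  expected <- sqrt(n_gwas) * 0.02
  expect_lt(abs(mean(stats) - expected), 3 * sd(stats) / sqrt(B))
})

test_that("simulate_de_table is null-calibrated and powered for planted shifts", {
  genes <- sprintf("G%03d", 1:400)
  null_tab <- simulate_de_table(genes, character(0), seed = 23)
  expect_lt(abs(mean(null_tab$p_uncorrected < 0.05) - 0.05), 0.03)

  de_genes <- genes[1:60]
  tab <- simulate_de_table(genes, de_genes, effect_sd = 1, seed = 24)
  hits <- filter_de(tab)
  sens <- length(intersect(hits, de_genes)) / length(de_genes)
  expect_gt(sens, 0.9)
  # both directions occur under the random sign
  expect_gt(sum(tab$log2fc[tab$true_de] > 0), 0)
  expect_gt(sum(tab$log2fc[tab$true_de] < 0), 0)

  expect_identical(simulate_de_table(genes[1:5], genes[1:2], seed = 9),
                   simulate_de_table(genes[1:5], genes[1:2], seed = 9))
})

test_that("generate_study round-trips through every reader and is byte-deterministic", {
  cfg <- sim_config(n_loci = 8, snps_per_locus = 6, genes_per_panel = 6,
                    n_go_terms = 10, planted_term_size = 4, seed = 55)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  unlink(c(d1, d2), recursive = TRUE)
  s1 <- generate_study(cfg, dir = d1)
  s2 <- generate_study(cfg, dir = d2)

  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  back <- read_study(d1)
  expect_equal(back$sumstats$z, s1$sumstats$z, tolerance = 1e-9)
  expect_equal(length(back$features), length(s1$features))
  expect_equal(unclass(back$ld[["GENE001"]]), unclass(s1$ld[["GENE001"]]),
               tolerance = 1e-9)
  expect_equal(back$de_table$p_uncorrected, s1$de_table$p_uncorrected,
               tolerance = 1e-9)
  expect_equal(back$go$terms$term_id, s1$go$terms$term_id)

  # generated artifacts satisfy their consuming types' invariants
  expect_s3_class(back$sumstats, "gwas_sumstats")
  truth <- s1$truth
  feat_genes <- unique(vapply(s1$features, `[[`, character(1), "gene"))
  expect_true(all(truth$causal_genes %in% feat_genes))
  expect_true(all(truth$planted_term %in% back$go$universe))
  expect_true("TERM_PLANTED" %in% back$go$terms$term_id)
})
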