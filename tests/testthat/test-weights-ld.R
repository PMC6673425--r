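test_that("load_weights keys features by (gene, panel) and rejects all-zero rows", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("GENE\tPANEL\tSNP\tWEIGHT",
               "G1\tNTR\trs1\t0.5", "G1\tNTR\trs2\t-0.2",
               "G2\tNTR\trs3\t0.9",
               "G1\tYFS\trs1\t0.1"), path)
  feats <- load_weights(path)
  expect_length(feats, 3)  # same gene in two panels = two features
  expect_named(feats, c("G1.NTR", "G2.NTR", "G1.YFS"))
  expect_equal(feats[["G1.NTR"]]$w, c(0.5, -0.2))

  zero <- tempfile(fileext = ".tsv")
  writeLines(c("GENE\tPANEL\tSNP\tWEIGHT", "G1\tNTR\trs1\t0"), zero)
  expect_error(load_weights(zero), "all-zero")
})

test_that("ld_matrix enforces symmetry and unit diagonal", {
  D <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_s3_class(ld_matrix(D), "ld_matrix")
  expect_error(ld_matrix(matrix(c(1, 0.4, 0.5, 1), 2,
                                dimnames = list(c("a","b"), c("a","b")))),
               "symmetric")
  expect_error(ld_matrix(matrix(c(2, 0.5, 0.5, 1), 2,
                                dimnames = list(c("a","b"), c("a","b")))),
               "diagonal")
})

test_that("regularize_psd clips negative eigenvalues and restores the diagonal", {
  # already PSD: returned unchanged
  expect_equal(regularize_psd(diag(3), eps = 0), diag(3))
  D_ok <- make_ld(5, 0.6)
  expect_lt(max(abs(regularize_psd(unclass(D_ok)) - unclass(D_ok))), 1e-10)

  # eigenvalues -0.2 and 2.2: projection must be PSD with unit diagonal
  D_bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  fixed <- regularize_psd(D_bad, eps = 0)
  e <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(e), -1e-8)
  expect_equal(diag(fixed), c(1, 1), tolerance = 1e-12)
  expect_equal(fixed, t(fixed))

  expect_error(regularize_psd(matrix(1, 2, 3)), "square")
})

test_that("align_feature intersects the three SNP sets in LD order and applies the overlap threshold", {
  ld <- make_ld(4, 0.5, snp_ids = c("s1", "s2", "s3", "s4"))
  fw <- feature_weights("G1", "NTR", c("s3", "s1", "s2", "s4"), c(0.3, 0.1, -0.2, 0.4))
  ss <- as.data.frame(list(snp_id = c("s2", "s1", "s3", "s4"),
                           z = c(2, 1, 3, 4)))

  af <- align_feature(fw, ss, ld, min_overlap_fraction = 0.5)
  expect_equal(af$snp_ids, c("s1", "s2", "s3", "s4"))  # LD order wins
  expect_equal(af$w, c(0.1, -0.2, 0.3, 0.4))
  expect_equal(af$z, c(1, 2, 3, 4))
  expect_equal(af$n_overlap, 4)
  expect_equal(af$overlap_fraction, 1)

  ss2 <- as.data.frame(list(snp_id = c("s1", "s3"), z = c(1, 3)))
  af2 <- align_feature(fw, ss2, ld, min_overlap_fraction = 0.5)
  expect_equal(af2$n_overlap, 2)
  expect_equal(af2$overlap_fraction, 0.5)

  ss3 <- as.data.frame(list(snp_id = "s1", z = 1))
  af3 <- align_feature(fw, ss3, ld, min_overlap_fraction = 0.5)
  expect_s3_class(af3, "skipped_feature")
  expect_match(attr(af3, "skip_reason"), "overlap")
})

test_that("the aligned statistic is invariant to input SNP ordering", {
  set.seed(42)
  ld <- make_ld(6, 0.4, snp_ids = paste0("s", 1:6))
  z <- rnorm(6)
  ss <- as.data.frame(list(snp_id = paste0("s", 1:6), z = z))
  w <- rnorm(6)
  base_af <- align_feature(feature_weights("G", "P", paste0("s", 1:6), w), ss, ld)
  base <- twas_zscore(base_af$w, base_af$z, base_af$D)
  for (i in 1:10) {
    perm <- sample(6)
    fw <- feature_weights("G", "P", paste0("s", perm), w[perm])
    ssp <- ss[sample(6), , drop = FALSE]
    af <- align_feature(fw, ssp, ld)
    expect_equal(twas_zscore(af$w, af$z, af$D), base, tolerance = 1e-12)
  }
})

test_that("LD matrices round-trip through the text formats", {
  D <- make_ld(4, 0.3, snp_ids = c("a", "b", "c", "d"))
  path <- tempfile(fileext = ".tsv")
  tab <- as.data.frame(unclass(D))
  utils::write.table(cbind(SNP = rownames(D), tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  back <- read_ld_matrix(path)
  expect_equal(unclass(back), unclass(D), tolerance = 1e-12)

  # headerless matrix + sidecar SNP list
  mpath <- tempfile(); spath <- tempfile()
  utils::write.table(unclass(D), mpath, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(D), spath)
  back2 <- read_ld_matrix(mpath, snp_file = spath)
  expect_equal(unname(unclass(back2)), unname(unclass(D)), tolerance = 1e-12)
  expect_equal(rownames(back2), c("a", "b", "c", "d"))
})
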