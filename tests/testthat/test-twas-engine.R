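test_that("twas_zscore matches hand-computed cases and the dense oracle", {
  # single SNP: reduces to sign(w) * z
  expect_equal(twas_zscore(2.0, 3.0, matrix(1)), 3.0)
  # antisymmetric weights on equal z cancel
  expect_equal(twas_zscore(c(1, -1), c(1, 1), diag(2)), 0)
  # correlated pair: 2.5 / sqrt(0.75)
  D <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(twas_zscore(c(0.5, 0.5), c(2, 3), D), 2.5 / sqrt(0.75),
               tolerance = 1e-12)
  # random cases against an independent elementwise evaluation
  set.seed(11)
  for (i in 1:20) {
    m <- sample(2:8, 1)
    Dm <- unclass(make_ld(m, runif(1, -0.8, 0.8)))
    w <- rnorm(m); z <- rnorm(m)
    expect_equal(twas_zscore(w, z, Dm), oracle_twas(w, z, Dm), tolerance = 1e-10)
  }
})

test_that("twas_zscore scaling invariances hold and degenerate w'Dw errors cleanly", {
  set.seed(12)
  D <- unclass(make_ld(5, 0.6))
  w <- rnorm(5); z <- rnorm(5)
  base <- twas_zscore(w, z, D)
  for (c_pos in c(0.01, 2, 1000)) {
    expect_equal(twas_zscore(c_pos * w, z, D), base, tolerance = 1e-10)
  }
  expect_equal(twas_zscore(-w, z, D), -base, tolerance = 1e-12)

  err <- tryCatch(twas_zscore(c(0, 0), c(1, 1), diag(2) * 0 + diag(1e-15, 2)),
                  error = function(e) e)
  expect_s3_class(err, "sumtwas_degenerate")
})

test_that("z_to_p is a stable two-sided tail: symmetric, monotone, no underflow at |z|=6+", {
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(1.959964), 0.05, tolerance = 1e-6)
  zs <- c(0.5, 1, 2, 4, 6, 8, 10, 30)
  p <- z_to_p(zs)
  expect_true(all(diff(p) < 0))          # monotone decreasing in |z|
  expect_true(all(p > 0))                # no underflow to zero
  expect_equal(z_to_p(-zs), p)           # symmetry
  expect_error(z_to_p(Inf), "finite")
})

test_that("genomic_lambda is 1 at the null median and matches a Monte-Carlo null", {
  # all |z| at the null median chi-square point
  expect_equal(genomic_lambda(rep(0.674490, 5)), 1.0, tolerance = 1e-5)
  expect_equal(genomic_lambda(c(0, 0, 0)), 0)
  expect_error(genomic_lambda(numeric(0)), "at least one")
  set.seed(314)
  expect_equal(genomic_lambda(rnorm(1e5)), 1.0, tolerance = 0.02)
})

test_that("twas_zscore is standard normal under z ~ MVN(0, D)", {
  set.seed(2718)
  m <- 12
  D <- make_ld(m, 0.65)
  Z <- simulate_gwas_z(D, rep(0, m), gwas_n = 1e5, n_draws = 30000)
  stats <- apply(Z, 1, function(z) {
    w <- simulate_weights(m, 0.4)
    twas_zscore(w, z, unclass(D))
  })
  expect_lt(abs(mean(stats)), 0.02)
  expect_lt(abs(var(stats) - 1), 0.05)
})

test_that("scan_panels composes features, records skips, and keeps p consistent with z", {
  set.seed(5)
  ld <- list(G1 = make_ld(4, 0.5, snp_ids = paste0("a", 1:4)),
             G2 = make_ld(4, 0.5, snp_ids = paste0("b", 1:4)))
  feats <- list(feature_weights("G1", "NTR", paste0("a", 1:4), rnorm(4)),
                feature_weights("G2", "NTR", paste0("b", 1:4), rnorm(4)),
                feature_weights("G3", "NTR", paste0("c", 1:4), rnorm(4)))
  ss <- as.data.frame(list(snp_id = c(paste0("a", 1:4), paste0("b", 1:2)),
                           z = rnorm(6)))
  res <- scan_panels(ss, feats, ld)
  # G2's overlap fraction is exactly 0.5, which meets the threshold
  expect_equal(res$gene, c("G1", "G2"))
  expect_true(all(res$p_twas == z_to_p(res$z_twas)))
  skipped <- attr(res, "skipped")
  expect_true(any(grepl("G3", skipped)))       # no LD for G3
})

test_that("a null scan has calibrated type-I error at alpha = 0.05", {
  set.seed(99)
  m <- 10
  D <- make_ld(m, 0.5)
  Z <- simulate_gwas_z(D, rep(0, m), gwas_n = 1e5, n_draws = 500)
  p <- apply(Z, 1, function(z) z_to_p(twas_zscore(simulate_weights(m, 0.5), z, unclass(D))))
  frac <- mean(p < 0.05)
  # binomial sd at n=500 is ~0.01; allow 3 sd
  expect_lt(abs(frac - 0.05), 0.03)
})
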