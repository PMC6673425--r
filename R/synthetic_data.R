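# Synthetic study generator: LD-structured GWAS z-scores, sparse
# multi-panel expression weights, a case/control DE table, and gene-set
# annotations, all with known ground truth.

#' Simulation configuration
#'
#' Collects every knob of the synthetic study in one validated list.
#' Defaults describe a desk-scale study with the structure the analysis
#' assumes: one cis locus per gene with AR(1) LD, three expression panels,
#' a GWAS at biobank meta-analysis scale, and a 20-case/20-control
#' microarray-style DE experiment.
#'
#' @param n_loci number of genes (= cis loci), default 60.
#' @param snps_per_locus SNPs per locus, default 20.
#' @param ld_rho AR(1) LD decay in (-1, 1), default 0.7.
#' @param panels expression-panel labels, default `c("NTR","YFS","METSIM")`.
#' @param genes_per_panel genes carried by each panel (sampled from the
#'   gene pool), default 40.
#' @param weight_sparsity fraction of locus SNPs with nonzero weight,
#'   default 0.3.
#' @param causal_fraction fraction of genes with a true expression-trait
#'   effect, default 0.1.
#' @param causal_effect per-gene standardized effect; the expected causal
#'   TWAS z-score is `sqrt(gwas_n) * causal_effect`. Default 0.01.
#' @param gwas_n GWAS sample size, default 446696 (40,585 cases +
#'   406,111 controls).
#' @param de_n_cases,de_n_controls DE group sizes, default 20 each.
#' @param de_effect_sd log2 mean shift magnitude for DE genes, default 1.
#' @param de_noise_sd per-sample log2 residual sd, default 0.5.
#' @param de_extra_fraction fraction of non-causal genes also made DE
#'   (so the DE list is not identical to the causal list), default 0.2.
#' @param n_go_terms number of random annotation terms, default 50.
#' @param planted_term_size size of the planted enriched term, default 10.
#' @param term_size_range size range for random terms, default `c(5, 25)`.
#' @param seed master seed, default 1.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_loci = 60, snps_per_locus = 20, ld_rho = 0.7,
                       panels = c("NTR", "YFS", "METSIM"),
                       genes_per_panel = 40, weight_sparsity = 0.3,
                       causal_fraction = 0.1, causal_effect = 0.01,
                       gwas_n = 446696,
                       de_n_cases = 20, de_n_controls = 20,
                       de_effect_sd = 1, de_noise_sd = 0.5,
                       de_extra_fraction = 0.2,
                       n_go_terms = 50, planted_term_size = 10,
                       term_size_range = c(5, 25), seed = 1) {
  cfg <- list(n_loci = n_loci, snps_per_locus = snps_per_locus,
              ld_rho = ld_rho, panels = as.character(panels),
              genes_per_panel = genes_per_panel,
              weight_sparsity = weight_sparsity,
              causal_fraction = causal_fraction,
              causal_effect = causal_effect, gwas_n = gwas_n,
              de_n_cases = de_n_cases, de_n_controls = de_n_controls,
              de_effect_sd = de_effect_sd, de_noise_sd = de_noise_sd,
              de_extra_fraction = de_extra_fraction,
              n_go_terms = n_go_terms,
              planted_term_size = planted_term_size,
              term_size_range = term_size_range, seed = seed)
  counts <- c("n_loci", "snps_per_locus", "genes_per_panel", "gwas_n",
              "de_n_cases", "de_n_controls", "n_go_terms",
              "planted_term_size", "seed")
  for (nm in counts) {
    assert_that(is.numeric(cfg[[nm]]) && cfg[[nm]] >= 1,
                sprintf("%s must be a positive count", nm))
  }
  assert_that(abs(ld_rho) < 1, "ld_rho must lie in (-1, 1)")
  assert_that(weight_sparsity > 0 && weight_sparsity <= 1,
              "weight_sparsity must lie in (0, 1]")
  assert_that(causal_fraction >= 0 && causal_fraction <= 1,
              "causal_fraction must lie in [0, 1]")
  assert_that(genes_per_panel <= n_loci,
              "genes_per_panel cannot exceed n_loci")
  assert_that(length(panels) >= 1, "need at least one panel")
  structure(cfg, class = "sim_config")
}

#' AR(1) LD matrix
#'
#' `D[i, j] = rho^|i - j|`: the minimal LD structure under which the TWAS
#' variance `w'Dw` differs from `w'w`. For |rho| < 1 the matrix is
#' positive definite with unit diagonal.
#'
#' @param size number of SNPs, >= 1.
#' @param rho decay parameter, |rho| < 1.
#' @param snp_ids optional ids; default `snp1..snpM`.
#' @return an [ld_matrix()].
#' @export
make_ld <- function(size, rho, snp_ids = paste0("snp", seq_len(size))) {
  assert_that(is.numeric(size) && size >= 1, "size must be >= 1")
  assert_that(abs(rho) < 1, "|rho| must be < 1")
  idx <- seq_len(size)
  D <- rho^abs(outer(idx, idx, "-"))
  ld_matrix(D, snp_ids = snp_ids)
}

#' Simulate a sparse cis expression-weight vector
#'
#' `ceil(sparsity * size)` positions chosen uniformly at random receive
#' standard-normal weights; the rest are zero. Always at least one nonzero
#' entry.
#'
#' @param size number of SNPs at the locus.
#' @param sparsity fraction of nonzero weights in (0, 1].
#' @param seed optional seed.
#' @return numeric weight vector of length `size`.
#' @export
simulate_weights <- function(size, sparsity, seed = NULL) {
  assert_that(size >= 1, "size must be >= 1")
  assert_that(sparsity > 0 && sparsity <= 1, "sparsity must lie in (0, 1]")
  with_seed(seed, {
    k <- max(1L, as.integer(ceiling(sparsity * size)))
    w <- numeric(size)
    w[sample.int(size, k)] <- stats::rnorm(k)
    # degenerate but possible: all k draws exactly 0 cannot happen a.s.
    w
  })
}

#' Simulate GWAS z-scores at a locus
#'
#' Draws from the standard summary-statistics model under LD:
#' \deqn{Z \sim MVN(\sqrt{n}\, D \beta,\; D)}
#' where `beta` is the joint per-SNP effect vector. With `beta = 0` this is
#' the null. A Cholesky factor of the (PSD-regularized) LD matrix generates
#' the correlated noise; pass `n_draws > 1` for replicate draws.
#'
#' @param D an LD matrix.
#' @param beta joint per-SNP effect vector (length `nrow(D)`).
#' @param gwas_n GWAS sample size.
#' @param seed optional seed.
#' @param n_draws number of independent locus draws, default 1.
#' @return numeric vector (one draw) or `n_draws x m` matrix.
#' @export
simulate_gwas_z <- function(D, beta, gwas_n, seed = NULL, n_draws = 1) {
  D <- as.matrix(D)
  m <- nrow(D)
  assert_that(length(beta) == m, "beta must match the LD dimension")
  assert_that(gwas_n >= 1, "gwas_n must be >= 1")
  mu <- sqrt(gwas_n) * drop(D %*% beta)
  L <- chol(regularize_psd(D, eps = 1e-10) + diag(1e-12, m))
  draws <- with_seed(seed, {
    E <- matrix(stats::rnorm(n_draws * m), n_draws, m)
    sweep(E %*% L, 2, mu, "+")
  })
  if (n_draws == 1) drop(draws) else draws
}

#' Per-SNP effect vector planting a causal feature
#'
#' Builds the joint effect vector `beta = effect * w / sqrt(w'Dw)` on the
#' feature's SNPs, standardized so the expected TWAS z-score of the causal
#' feature is exactly `sqrt(gwas_n) * effect`:
#' `E[z_twas] = sqrt(n) w'D beta / sqrt(w'Dw) = sqrt(n) * effect`.
#'
#' @param fw a [feature_weights()].
#' @param ld the locus [ld_matrix()] (needed for the `w'Dw` scaling).
#' @param effect standardized effect size; 0 returns a zero vector.
#' @return numeric beta vector in the LD matrix's SNP order.
#' @export
plant_causal <- function(fw, ld, effect) {
  m <- nrow(ld)
  beta <- numeric(m)
  if (effect == 0) return(beta)
  idx <- match(fw$snp_ids, rownames(ld))
  assert_that(!anyNA(idx), "feature SNPs must all be in the LD matrix")
  w_full <- numeric(m)
  w_full[idx] <- fw$w
  denom <- sqrt(drop(crossprod(w_full, unclass(ld) %*% w_full)))
  assert_that(denom > 0, "w'Dw must be positive to plant a causal effect")
  effect * w_full / denom
}

#' Simulate a case/control differential-expression table
#'
#' Per gene, log2 expression is drawn normal per sample in each group;
#' genes in `de_genes` receive a mean shift of magnitude `effect_sd` with
#' random sign (so both up- and down-regulation occur). The reported fold
#' change is `2^(mean_case - mean_control)` and the p-value comes from a
#' two-sample t-test on the simulated values.
#'
#' @param genes character vector of gene symbols.
#' @param de_genes genes receiving a true shift.
#' @param n_cases,n_controls group sizes, default 20 each.
#' @param effect_sd log2 shift magnitude for DE genes, default 1.
#' @param noise_sd per-sample residual sd on the log2 scale, default 0.5.
#' @param seed optional seed.
#' @return data frame with `gene`, `fold_change`, `p_uncorrected` (the
#'   DE-table contract) plus `true_de` and `log2fc`.
#' @export
simulate_de_table <- function(genes, de_genes, n_cases = 20, n_controls = 20,
                              effect_sd = 1, noise_sd = 0.5, seed = NULL) {
  assert_that(n_cases >= 2 && n_controls >= 2, "need >= 2 samples per group")
  with_seed(seed, {
    rows <- lapply(genes, function(g) {
      shift <- if (g %in% de_genes) sample(c(-1, 1), 1) * effect_sd else 0
      cases <- stats::rnorm(n_cases, mean = shift, sd = noise_sd)
      ctrls <- stats::rnorm(n_controls, mean = 0, sd = noise_sd)
      lfc <- mean(cases) - mean(ctrls)
      p <- stats::t.test(cases, ctrls)$p.value
      data.frame(gene = g, fold_change = 2^lfc, p_uncorrected = p,
                 true_de = g %in% de_genes, log2fc = lfc,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate gene-set annotations with one planted term
#'
#' Random term memberships with sizes drawn uniformly from
#' `term_size_range`, plus one term whose members are exactly
#' `planted_term`. The universe is the full gene list. Random terms get
#' category BP or MF at random, the planted term gets BP.
#'
#' @param genes universe gene list.
#' @param n_terms number of random terms.
#' @param planted_term character vector of planted-term members
#'   (must be a subset of `genes`).
#' @param term_size_range size range for the random terms, default
#'   `c(5, 25)` (capped at the universe size).
#' @param seed optional seed.
#' @return a [gene_set_collection()]; the planted term has id
#'   `"TERM_PLANTED"`.
#' @export
simulate_go <- function(genes, n_terms, planted_term,
                        term_size_range = c(5, 25), seed = NULL) {
  assert_that(all(planted_term %in% genes),
              "planted_term must be a subset of the gene universe")
  assert_that(length(planted_term) >= 1, "planted_term must be non-empty")
  with_seed(seed, {
    lo <- min(term_size_range); hi <- min(max(term_size_range), length(genes))
    sizes <- sample(seq(lo, hi), n_terms, replace = TRUE)
    members <- lapply(sizes, function(s) sample(genes, s))
    ids <- sprintf("TERM_%04d", seq_len(n_terms))
    terms <- data.frame(
      term_id = c(ids, "TERM_PLANTED"),
      name = c(paste("random term", seq_len(n_terms)), "planted term"),
      category = c(sample(c("BP", "MF"), n_terms, replace = TRUE), "BP"),
      stringsAsFactors = FALSE)
    terms$members <- c(members, list(as.character(planted_term)))
    gene_set_collection(terms, universe = genes)
  })
}

#' Generate a complete synthetic study
#'
#' Produces every input the pipeline consumes — summary statistics,
#' per-feature expression weights across the configured panels, per-locus
#' LD matrices, a DE table, gene-set annotations — together with the
#' ground truth (causal genes, DE genes, planted term, per-locus beta).
#' Fully deterministic per `config$seed`. When `dir` is given, all inputs
#' are also written in the text formats the readers consume, and written
#' files round-trip loss-free.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; created if missing.
#' @return list with `sumstats`, `features`, `ld` (named by gene),
#'   `de_table`, `go` and `truth` (list: `causal_genes`, `de_genes`,
#'   `planted_term`, `beta` per gene, `config`).
#' @export
generate_study <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    genes <- sprintf("GENE%03d", seq_len(cfg$n_loci))
    # each gene owns one locus; SNP ids are globally unique
    ld <- list()
    snp_ids_by_gene <- list()
    for (i in seq_along(genes)) {
      ids <- sprintf("rs%03d_%02d", i, seq_len(cfg$snps_per_locus))
      ld[[genes[i]]] <- make_ld(cfg$snps_per_locus, cfg$ld_rho, snp_ids = ids)
      snp_ids_by_gene[[genes[i]]] <- ids
    }
    # panel memberships and sparse weights
    features <- list()
    for (p in cfg$panels) {
      carried <- sort(sample(genes, cfg$genes_per_panel))
      for (g in carried) {
        w <- simulate_weights(cfg$snps_per_locus, cfg$weight_sparsity)
        features[[paste(g, p, sep = ".")]] <-
          feature_weights(g, p, snp_ids_by_gene[[g]], w)
      }
    }
    # causal genes: planted through their first carrying panel's weights
    n_causal <- round(cfg$causal_fraction * cfg$n_loci)
    feat_genes <- unique(vapply(features, `[[`, character(1), "gene"))
    causal_genes <- if (n_causal > 0) sort(sample(feat_genes, min(n_causal, length(feat_genes)))) else character(0)
    beta <- lapply(genes, function(g) numeric(cfg$snps_per_locus))
    names(beta) <- genes
    for (g in causal_genes) {
      fw <- features[[which(vapply(features, function(f) f$gene == g, logical(1)))[1]]]
      beta[[g]] <- plant_causal(fw, ld[[g]], cfg$causal_effect)
    }
    # GWAS z-scores locus by locus
    z_all <- unlist(lapply(genes, function(g) {
      simulate_gwas_z(ld[[g]], beta[[g]], cfg$gwas_n)
    }))
    all_snps <- unlist(snp_ids_by_gene, use.names = FALSE)
    sumstats <- as_gwas_sumstats(data.frame(
      snp_id = all_snps,
      chrom = rep(as.character(seq_along(genes)), each = cfg$snps_per_locus),
      pos = rep(seq_len(cfg$snps_per_locus) * 1000L, times = length(genes)),
      allele_effect = "A", allele_other = "G",
      z = z_all, stringsAsFactors = FALSE))
    # DE truth: all causal genes plus a slice of the rest
    others <- setdiff(genes, causal_genes)
    n_extra <- round(cfg$de_extra_fraction * length(others))
    de_genes <- sort(c(causal_genes, sample(others, n_extra)))
    de_table <- simulate_de_table(genes, de_genes,
                                  n_cases = cfg$de_n_cases,
                                  n_controls = cfg$de_n_controls,
                                  effect_sd = cfg$de_effect_sd,
                                  noise_sd = cfg$de_noise_sd)
    # planted term: the causal-and-DE genes, padded to the configured size
    core <- intersect(causal_genes, de_genes)
    pad <- setdiff(de_genes, core)
    planted <- core
    if (length(planted) < cfg$planted_term_size) {
      take <- min(cfg$planted_term_size - length(planted), length(pad))
      planted <- c(planted, sample(pad, take))
    }
    planted <- sort(planted)
    go <- simulate_go(genes, cfg$n_go_terms, planted,
                      term_size_range = cfg$term_size_range)
    truth <- list(causal_genes = causal_genes, de_genes = de_genes,
                  planted_term = planted, beta = beta, config = cfg)
    study <- list(sumstats = sumstats, features = features, ld = ld,
                  de_table = de_table, go = go, truth = truth)
    if (!is.null(dir)) write_study(study, dir)
    study
  })
}

#' Write a synthetic study to disk
#'
#' Emits `sumstats.tsv`, `weights.tsv`, per-gene `ld_<gene>.tsv`,
#' `de_table.tsv`, `annotations.gmt` and `truth.tsv` (role-labelled) in
#' exactly the formats the pipeline readers consume.
#'
#' @param study output of [generate_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- study$sumstats
  utils::write.table(
    data.frame(SNP = ss$snp_id, CHR = ss$chrom, BP = ss$pos,
               A1 = ss$allele_effect, A2 = ss$allele_other,
               Z = sprintf("%.10g", ss$z)),
    file.path(dir, "sumstats.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  wrows <- do.call(rbind, lapply(study$features, function(f) {
    data.frame(GENE = f$gene, PANEL = f$panel, SNP = f$snp_ids,
               WEIGHT = sprintf("%.10g", f$w), stringsAsFactors = FALSE)
  }))
  utils::write.table(wrows, file.path(dir, "weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(study$ld)) {
    D <- study$ld[[g]]
    tab <- as.data.frame(formatC(unclass(D), format = "g", digits = 10))
    names(tab) <- rownames(D)
    utils::write.table(cbind(data.frame(SNP = rownames(D)), tab),
                       file.path(dir, sprintf("ld_%s.tsv", g)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  de <- study$de_table
  utils::write.table(
    data.frame(GENE = de$gene, FC = sprintf("%.10g", de$fold_change),
               P = sprintf("%.10g", de$p_uncorrected)),
    file.path(dir, "de_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(study$go, file.path(dir, "annotations.gmt"))
  truth <- study$truth
  troles <- rbind(
    data.frame(ROLE = "causal_gene", ITEM = truth$causal_genes),
    data.frame(ROLE = "de_gene", ITEM = truth$de_genes),
    data.frame(ROLE = "planted_term_gene", ITEM = truth$planted_term))
  utils::write.table(troles, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a written study back into pipeline objects
#'
#' Round-trips the text outputs of [write_study()] through the package's
#' own readers.
#'
#' @param dir directory written by [write_study()].
#' @return list with `sumstats`, `features`, `ld`, `de_table`, `go`.
#' @export
read_study <- function(dir) {
  ss <- read_sumstats(file.path(dir, "sumstats.tsv"))
  features <- load_weights(file.path(dir, "weights.tsv"))
  ld_files <- list.files(dir, pattern = "^ld_.*\\.tsv$", full.names = TRUE)
  ld <- lapply(ld_files, read_ld_matrix)
  names(ld) <- sub("^ld_(.*)\\.tsv$", "\\1", basename(ld_files))
  de <- read_de_table(file.path(dir, "de_table.tsv"))
  go <- read_gmt(file.path(dir, "annotations.gmt"))
  list(sumstats = ss, features = features, ld = ld, de_table = de, go = go)
}
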