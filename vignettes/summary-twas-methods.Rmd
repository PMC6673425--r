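---
title: "Summary-based TWAS with permutation filtering: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-based TWAS with permutation filtering: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumtwas)
```

## The statistical model

A transcriptome-wide association study from summary data asks whether the
genetically predicted cis expression of a gene is associated with a trait,
using only per-SNP GWAS z-scores rather than individual-level genotypes.
For one gene-tissue feature, let `w` be the cis expression weights trained
in an expression reference panel, `Z` the GWAS z-scores at the same SNPs,
and `D` the SNP-correlation (LD) matrix at the locus. The association
statistic is the standardized linear combination

$$Z_{TWAS} = \frac{w'Z}{\sqrt{w'Dw}}.$$

Under the null, summary z-scores at a locus are well described by
`Z ~ MVN(0, D)`, so `w'Z` has variance `w'Dw` and the statistic is standard
normal; its p-value is the two-sided normal tail. The two-sided convention
is fixed by internal consistency of published z/p pairs for this statistic
(a z of 6.2053 pairs with p = 5.46e-10 only under the two-sided tail). The
tail is computed on the upper side directly (`pnorm(|z|, lower.tail =
FALSE)`); the naive `1 - pnorm(z)` cancels to zero already around |z| = 8
and would destroy exactly the top hits the method exists to find.

The genomic inflation factor summarizes calibration across all tested
features: `lambda = median(Z_TWAS^2) / qchisq(0.5, 1)`, the median observed
1-df chi-square over its null median (0.4549). Values near 1 indicate a
calibrated scan; modest inflation is expected when the upstream weight
training reports only each gene's best predictive model.

### The permutation filter

A large TWAS statistic can arise without any expression-trait relation:
when the GWAS signal at a locus is strong and LD extensive, almost any
weight vector picks it up (by-chance QTL co-localization). The filter
shuffles the weight entries uniformly across the locus's SNP positions,
recomputes the statistic with `Z` and `D` fixed — conditioning on the
observed GWAS signal — and reports the add-one empirical p-value

$$p_{perm} = \frac{\#\{|Z_{perm}| \ge |Z_{obs}|\} + 1}{B + 1},$$

which is never zero, bounded below by `1/(B+1)`, and super-uniform under
exchangeable weights. Extremeness is two-sided, matching the analytic p.
Ties (a permutation reproducing the observed arrangement) count as extreme,
with a small relative tolerance so the tie survives floating-point
round-off. The exact permutation scheme used by upstream weight-training
software is not published in detail; the uniform shuffle is documented here
as the package's scheme, and the single-SNP degenerate case (only one
arrangement, hence p = 1) falls out of it naturally. Per-feature sub-seeds
are derived by hashing (master seed, gene, panel), so results are
independent of scan order and safe to parallelize.

## Pipeline stages and their thresholds

| Stage | Rule | Default | Why |
|---|---|---|---|
| TWAS significance | `p_twas < p` and `p_perm < p`, strict | 0.05 / 0.05 | the conventional transcriptome-wide screen with QTL-co-localization control |
| Bonferroni report | `p_twas < alpha / m` | alpha 0.05, m = features tested | family-wise control over all gene-tissue features |
| DE filter | `max(FC, 1/FC) > fc` and `p < p_de` | fc 1.2, p 0.05 | a deliberately relaxed microarray screen; symmetric because both induced and depressed expression are biologically relevant |
| Intersection | case-insensitive exact symbol match, feature level first | — | see below |
| Enrichment | hypergeometric upper tail, raw `p < 0.05` | method `"hypergeometric"` | EASE variant available; BH q-values optional |

All inequalities are strict, matching how such thresholds are printed
("P < 0.05", "fold change > 1.2"); rows sitting exactly at a threshold are
excluded.

Design choices that were genuinely open:

* **DE direction.** The literal reading of "fold change > 1.2" keeps only
  up-regulated genes; the `symmetric` default also keeps `FC < 1/1.2`,
  because depressed expression is routinely treated as differential
  expression in the studies this pipeline consumes. `up_only` is provided
  for the literal reading.
* **Intersection order.** Intersecting at the feature level and then
  collapsing to unique genes is fixed (the alternative — collapse first —
  gives the same gene list but loses the per-panel feature counts the
  report needs).
* **Allele harmonization.** Summary files rarely share the LD panel's
  allele orientation. Defaults: flip the z sign on swapped alleles, resolve
  clean strand flips, drop strand-ambiguous A/T and C/G SNPs (their
  orientation is unresolvable from alleles alone and a silent sign error
  corrupts `w'Z` undetectably). Both behaviours are configurable; audit
  counts always partition the input exactly.
* **Gene matching** is exact symbol, case-insensitive. Alias and probe-set
  mapping need an external resource and are out of scope; mismatched
  symbols therefore reduce the overlap rather than silently inflating it.
* **EASE vs Fisher.** Which statistic produced any given published
  enrichment table is often unstated; both are provided and neither is
  claimed to reproduce a specific tool's annotation database. The module
  consumes user-supplied GMT annotations; the default universe is the
  union of all term members, configurable to a user list.

## Numerical choices

* `w'Dw` below `1e-10` makes the statistic undefined; such features raise a
  typed condition and become skip records in the scan, never silent drops.
* LD matrices are projected to the PSD cone by eigenvalue clipping at
  `eps = 1e-8` followed by a `cov2cor` rescale to unit diagonal — a
  numerical floor only, distorting a valid correlation matrix by less than
  `1e-10`.
* Features with weight/GWAS SNP overlap below `min_overlap_fraction = 0.5`
  are skipped with a logged reason: a statistic computed from a small
  remnant of the trained weight vector no longer tests the trained
  predictor.
* The canonical SNP order for an aligned feature is the LD matrix's order;
  the statistic is invariant to any input ordering of weights or summary
  rows (property-tested).
* Ranking ties are broken deterministically: ascending p then gene symbol
  in reports, term id in enrichment.

## What the synthetic generator emulates — and what it does not

`generate_study()` produces every pipeline input with known truth, at the
structure the analysis assumes. The defaults were chosen once as a
desk-scale caricature of a real integrative study and are deliberately not
tuning knobs:

* **LD**: one cis locus per gene, 20 SNPs, AR(1) correlation
  `D[i,j] = rho^|i-j|` with `rho = 0.7` — the minimal structure under which
  `w'Dw` differs from `w'w`, so the LD adjustment is actually exercised.
  Block layouts can be composed by the caller.
* **Weights**: three panels (NTR, YFS, METSIM labels) each carrying 40 of
  60 genes; 30% of locus SNPs get standard-normal weights (cis predictors
  are sparse).
* **GWAS**: `Z ~ MVN(sqrt(n) D beta, D)` — the standard summary-statistics
  likelihood — with `n = 446,696`, the scale of a large stroke
  meta-analysis (40,585 cases + 406,111 controls). Causal genes (10%) get
  `beta = effect * w / sqrt(w'Dw)` so the expected causal statistic has the
  closed form `sqrt(n) * effect`; the default `effect = 0.01` puts it near
  6.7, comparable to a genuine top hit.
* **DE experiment**: 20 cases vs 20 controls, per-sample log2 expression
  with residual sd 0.5; DE genes (all causal genes plus 20% of the rest)
  receive a 1 log2-unit mean shift with random sign, so the symmetric
  filter mode is exercised; fold change is `2^(mean difference)` and p
  comes from a two-sample t-test.
* **Annotations**: 50 random terms of size 5–25 plus one planted term built
  from the causal-and-DE genes (padded to size 10 with other DE genes).

Passing tests on this generator show that the statistic is calibrated under
the assumed null, that the permutation and enrichment engines agree with
exhaustive enumeration, and that a strong planted signal flows through
every stage to the final report. They do **not** show robustness to what
real data add: allele-frequency-dependent LD estimated from a finite
reference (here LD is known exactly), weight-training noise and model
selection, sample overlap between GWAS and reference panels, probe-to-gene
mapping errors, batch structure in the expression experiment, or annotation
bias in real GO databases. Published enrichment p-values from proprietary
annotation snapshots are therefore not reproduction targets for this
module.

## Problem sizes used in validation

The bundled checks run at desk scale, chosen as the package's own
validation budget: 10,000 simulated null loci for calibration of the
statistic's mean, variance, type-I error and lambda; 30,000 permutations
against the 6-arrangement exhaustive oracle; the full enumeration sweep of
the hypergeometric tail for every universe size up to 12; and one complete
synthetic study (120 features, 1,000 permutations per feature) for
planted-truth recovery.

## Known limitations

* No conditional/joint analysis of multiple features per locus, no
  colocalization or fine-mapping: one feature is one test.
* Weight training from individual-level data is upstream and out of scope;
  the package consumes trained weights in a plain long-format table.
* The DE stage consumes a (gene, fold change, p) table; the underlying
  multi-factor ANOVA and probe summarization belong to the upstream
  expression study.
* Genome-build liftover, INFO-score filtering and binary genotype formats
  are out of scope; summary files are expected pre-filtered.
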