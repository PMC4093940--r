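---
title: "mirsnp: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirsnp: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsnp)
```

## What the package computes

mirsnp is an inference chain linking quantitative-trait association signals
to miRNA-mediated regulation. Its stages, each usable on its own:

1. **Association scan** (`scan_trait`): per-variant OLS of a quantitative
   trait on allele dosage, adjusted for covariates (age in years, sex coded
   0/1, education in years) and genotype principal components
   (`compute_pcs`); greedy ±1 Mb clumping of results into loci
   (`clump_loci`).
2. **LD proxy search** (`compute_r2`, `find_proxies`): expand an index SNP
   to the variants in strong linkage disequilibrium with it.
3. **Allele-aware target-site prediction** (`find_seed_sites`,
   `align_score`, `duplex_energy`, `call_consensus`, `allele_delta`,
   `map_snps_to_sites`): canonical seed sites in 3'UTRs, a k-of-n scorer
   consensus, and the change in consensus site score between the two alleles
   of a SNP inside a site.
4. **Permutation enrichment** (`flag_genes`, `permutation_test`): do a
   miRNA's target genes carry trait-associated SNPs more often than
   non-target genes?
5. **eQTL stage** (`iqr_filter`, `normality_check`, `fit_eqtl`,
   `sensitivity_excluding_genotype`): covariate-adjusted additive regression
   of expression on minor-allele count with explicit outlier rules.
6. **Reporter statistics** (`reporter_analysis` and its parts): scrambled-
   control normalization of luciferase assays, one-sample binding tests,
   the two-sample allele test, and the allele effect in percentage points.

A synthetic-data module (`gen_panel`, `gen_cohort`, `gen_phenotype`,
`gen_targetome`, `gen_expression`, `gen_plate`) generates inputs with the
statistical structure each stage assumes, plus ground-truth tables, so the
whole chain runs and is testable with no downloads.

## Models and assumptions

### Association scan

The model is `y = b0 + b*g + C*gamma + e` with `g` the expected alt-allele
dosage in `[0, 2]`. Imputed genotypes are handled by regression on expected
dosage rather than an integrated missing-data likelihood; for well-imputed
common variants the two are asymptotically equivalent, and dosage regression
keeps the stage free of special-purpose machinery. Missing dosages are
mean-imputed per variant at fit time only — raw data are never modified.
Complete cases are required for trait and covariates. Two-sided P-values
come from the t distribution with `n - p` degrees of freedom.

Degenerate-input policy (documented, tested): a monomorphic variant emits an
NA row with reason `"monomorphic"`; a constant trait emits beta 0, t 0,
p 1 with reason `"constant_trait"`; a collinear design emits reason
`"collinear"`.

Thresholds: genome-wide 5e-8 and suggestive 1e-6, both configurable. No
multiple-testing correction is applied across traits (a documented caveat,
matching common single-trait reporting practice). The ±1 Mb greedy merge
defining a locus is this package's choice; "distinct region" has no
universal definition.

### LD r²

Haplotype mode is the textbook `r² = D²/(pA(1-pA) pB(1-pB))` from phased 0/1
haplotypes. Genotype mode is the squared Pearson correlation of dosages
(composite LD) — an approximation for unphased cohorts, exact when all
individuals are homozygous. The proxy default is r² ≥ 0.8 with a ±1 Mb
window; a relaxed 0.5 sweep is available because both thresholds are in
legitimate use for proxy searches, and the discrepancy should be surfaced,
not hidden. No EM haplotype-frequency estimation is attempted.

### Seed sites and the two auxiliary scorers

The seed is miRNA positions 2–8 from the 5' end. Site classes on the mRNA
(written 5'→3', the reverse complement of the seed, t1 A at the 3' end):
8mer (match 2–8 + t1 A), 7mer-m8 (match 2–8), 7mer-A1 (match 2–7 + t1 A),
6mer (match 2–7). The t1 A is required as an A in the mRNA regardless of the
miRNA's first base, the standard canonical-site convention. At one
seed-match locus only the longest class is reported; overlapping loci are
all reported.

Because the specific third-party predictors behind published consensus
calls are not redistributable, the consensus here is built from three
transparent scorers with the same decision structure (k-of-n vote,
default 3 of 3):

* the seed-class caller (any canonical class supports the site);
* a complementarity alignment score: local DP with Watson–Crick +5, G:U
  wobble +2, mismatch −3, gap open −8, gap extend −2, seed positions ×2,
  over the site plus 15 nt of 5' flank (where the miRNA 3' region pairs);
  support at ≥ 55 — any clean seed pairing scores ≥ 60, so the cutoff
  demands little more than the seed itself;
* a seed duplex stability: nearest-neighbor stack energies over the seed
  duplex from a published-style RNA/RNA table (all entries negative; G:U
  stacks +1 each; t1 A bonus −0.3); support at ≤ −7 kcal/mol, which passes
  seeds with some G/C stacking and fails weak all-A/U seeds.

Absolute parameter values are declared, not fitted; only their relative
behavior is load-bearing, and the tests exercise exactly that (monotonicity,
cutoff straddling, oracle equality for the seed caller).

### Allele delta

For a SNP at a UTR offset, the consensus site score — the sum over called
sites overlapping the SNP of `class weight + alignment/75 + max(0,
−energy)/10` — is computed under each allele; `delta = score_alt −
score_ref`. The direction convention is biological: weakened binding under
the alternative allele (`delta < 0`) predicts de-repression, i.e. expression
direction "up". The definition makes `delta` exactly antisymmetric under
swapping the allele labels, which the tests assert for every planted
miR-SNP. Scoring uses `k_min = 1` by default so that a site losing even one
class level registers; the consensus `k_min = 3` remains the default for
site *calling*.

### Enrichment

The enrichment statistic is declared (the underlying analysis choice is not
otherwise recoverable): difference in the proportion of associated genes
between target and non-target genes, with the null built by permuting
target labels (preserving counts), default 100,000 permutations, and the
add-one estimator `(b+1)/(B+1)` so the empirical P is always in (0, 1].
SNP-to-gene assignment is positional with a ±10 kb margin, assign-to-all on
overlap, association cutoff p ≤ 1e-4 — all configurable. Permuting gene
labels ignores LD between SNPs of neighboring genes; a SNP-level rotation
scheme is out of scope and the limitation is stated here deliberately.

### eQTL stage

Expression outliers are removed by the 1.5×IQR fence rule with
linear-interpolation quartiles (R's default quantile type 7); fences are
inclusive. The quantile convention is exposed because borderline exclusion
counts are convention-sensitive. The Shapiro–Wilk check (delegated to
`stats::shapiro.test`, cross-checked in the tests against an independent
implementation) is advisory and never gates the fit. The regression reports
beta per **minor** allele: if the alt allele is the major one the dosage is
flipped to `2 - d` (flagged in the result). Factor covariates such as
population of origin are expanded to indicators with the first level
dropped. The homozygote-exclusion sensitivity analysis filters outliers on
the full vector first, then drops the genotype class, then refits — the
order that matches the original sequential analysis.

### Reporter statistics

Within each experiment and construct, the targeting-miRNA mean is divided
by the scrambled-control mean; per-experiment ratios are the analysis unit.
The binding test is a one-sample t of ratios against 1, one-tailed (lower:
binding suppresses expression). The allele test is a two-sample t, two-
tailed, Welch by default (pooled by option; which was used originally is
unstated). The allele effect is reported as the **difference of normalized
means ×100** — percentage points, not a ratio: with means 0.703 and 0.585
this reads 11.8, matching the arithmetic of the published worked values,
whereas the ratio reading (≈20.2%) does not. The 3-SD outlier rule is
applied per condition before normalization (order configurable via
`filter_k = Inf`).

A caution the tests encode: with mean and SD computed from all n values of
a condition (the stated single-pass rule), a lone outlier can deviate at
most `(n−1)/√n` SDs — about 2.04 at n = 6 — so the 3-SD rule cannot flag a
single wild replicate among six. The rule is implemented as stated; the
bound is documented rather than silently "fixed".

## The synthetic world: what it emulates, what it does not

* `gen_panel` models LD as a founder-copying block mosaic: within a block
  every haplotype copies one of a few founders (with per-site mutation);
  founder choice re-randomizes between blocks. This produces the two
  regimes the proxy stage distinguishes — r² near 1 within blocks, near 0
  between — and is exactly analyzable (2 founders, no mutation: all
  within-block pairs have r² = 1). It has no recombination-map or
  coalescent realism, no allele-frequency spectrum, no population
  structure.
* `gen_phenotype` draws age ~ Uniform(60, 80) (an aged cohort), sex ~
  Bernoulli(0.5), education ~ Normal(13, 3) truncated to [8, 20] years;
  only the shapes matter, since the covariates exist to exercise
  adjustment.
* `gen_targetome` plants canonical sites (class uniform over the four) and
  site-breaking SNPs whose ref allele matches the site and whose alt allele
  breaks complementarity; backgrounds are rejection-sampled so no
  accidental ≥6mer match for any supplied miRNA exists and the alt allele
  creates no new site. Real UTRs have composition bias, conservation and
  non-canonical sites; none of that is modeled, so a green recovery test
  establishes correctness of the calling machinery, not predictive accuracy
  on real transcripts.
* `gen_expression` uses the scale of normalized small-RNA quantifications
  (intercept 400, per-allele effect 80, residual SD 120) and plants a
  fraction of ±1000 shifts to exercise the IQR filter.
* `gen_plate` puts the experiment-level baseline jitter (log-normal,
  SD 0.2) in a factor shared by all four conditions of an experiment, so it
  cancels exactly in normalized ratios; replicate noise is multiplicative
  with CV 0.08. That CV sits in the typical 5–15% technical range of
  plate-reader luminescence and satisfies the stated recovery calibration
  (an allele effect of 0.118 recovered within ±0.03 in ≥90% of runs at
  7 experiments × 6 replicates needs a per-ratio SD below ~0.034, i.e.
  CV ≲ 0.09). Published between-experiment SEs (~0.03–0.04 at n = 7) imply
  additional biological experiment-to-experiment variance in the *ratio*
  itself that this generator deliberately does not model; with it, the
  ±0.03/90% calibration would not be attainable at this replicate
  structure.

Every generator is a pure function of its parameters and seed
(`withr::with_seed`), and every planted object is recorded in a truth table
that the recovery tests resolve.

## Numerical choices

* OLS via Cholesky normal equations (`chol2inv(chol(crossprod(X)))`): the
  designs are tiny and well-conditioned; a collinear design is caught and
  reported per variant rather than aborting a scan.
* r² is clamped to [0, 1] against floating-point overshoot.
* Permutation P uses add-one; ties at the observed statistic count toward
  the numerator (the conservative direction).
* `iqr_filter` is *near*-idempotent: re-fitted fences shrink after
  trimming, so a second pass occasionally removes more points (4 of 50
  fixed-seed Gaussian instances in the property test). The test logs and
  bounds the violation rate instead of asserting strict idempotence, which
  does not hold.
* The seed-site caller determines the class at each 6mer core position by
  checking the m8 and t1 extensions, which reports exactly one (the
  longest) class per locus — equivalent to, and tested against, exhaustive
  window enumeration with suppression.

## External reproduction

The one analysis that needs external data — the eQTL reproduction on the
GEUVADIS miRNA quantifications with 1000 Genomes genotypes for rs9882688
(expected: 24 of 333 European samples excluded by the IQR rule; beta ≈
80.87, SE ≈ 23.00; sensitivity beta ≈ 77.35 at n = 307) — runs only when
the user supplies the downloads; see `?geuvadis_paths` for the expected
file locations and the genotype-table format. Everything else in the test
suite is desk-scale and runs unconditionally.

## Known limitations

* No mixed models, kinship or genomic-control correction in the scan.
* No EM haplotype phasing; genotype-mode r² is composite LD.
* No machine-learned site scoring, no site-accessibility folding, no
  non-canonical (bulged/centered) sites; biallelic SNPs only.
* The enrichment permutation ignores SNP-level LD structure.
* Expression inputs are assumed pre-normalized; no normalization pipeline.
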