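# Permutation test for enrichment of trait-associated SNPs in a miRNA's
# target genes.

#' Reduce association rows and site calls to per-gene flags
#'
#' A SNP is assigned to every gene whose interval, extended by `margin_bp` on
#' each side, contains its position (assign-to-all on overlap). A gene is
#' `is_associated` when any assigned SNP has `p <= p_assoc` (inclusive), and
#' `is_target` when any consensus site call lands in any transcript of the
#' gene.
#'
#' @param assoc_rows association rows from [scan_trait()].
#' @param gene_intervals data.frame from [read_gene_intervals()].
#' @param target_genes character vector of gene symbols carrying a consensus
#'   target-site call (e.g. unique genes of [map_snps_to_sites()] or of
#'   consensus calls across a targetome).
#' @param p_assoc association cutoff (default 1e-4).
#' @param margin_bp assignment margin (default 1e4).
#' @return data.frame: gene_symbol, is_target, is_associated (one row per
#'   gene).
#' @export
flag_genes <- function(assoc_rows, gene_intervals, target_genes,
                       p_assoc = 1e-4, margin_bp = 1e4L) {
  if (nrow(gene_intervals) == 0L) stop("flag_genes: empty gene set")
  g <- gene_intervals
  assoc <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    hit <- assoc_rows$chrom == g$chrom[i] &
      assoc_rows$pos >= g$start[i] - margin_bp &
      assoc_rows$pos <= g$end[i] + margin_bp
    assoc[i] <- any(hit & !is.na(assoc_rows$p) & assoc_rows$p <= p_assoc)
  }
  data.frame(gene_symbol = g$gene_symbol,
             is_target = g$gene_symbol %in% target_genes,
             is_associated = assoc, stringsAsFactors = FALSE)
}

#' Permutation test for target-gene enrichment of associated SNPs
#'
#' Observed statistic: proportion of associated genes among targets minus
#' the proportion among non-targets. The null is built by permuting the
#' `is_target` labels (preserving the target count) `B` times; the one-sided
#' empirical P uses the add-one rule `p = (b + 1) / (B + 1)` where `b` counts
#' permutations with statistic >= observed, so P is always in `(0, 1]`.
#'
#' @param flags data.frame from [flag_genes()].
#' @param B number of permutations (default 1e5).
#' @param seed RNG seed.
#' @return list of class `enrichment_result`: statistic, n_perm,
#'   p_empirical, n_target, n_gene.
#' @export
permutation_test <- function(flags, B = 1e5L, seed = 1L) {
  stopifnot(B >= 1L)
  x <- as.integer(flags$is_associated)
  tg <- flags$is_target
  n <- length(x); nt <- sum(tg)
  if (nt == 0L || nt == n)
    stop("permutation_test: statistic undefined when all or no genes are targets")
  total <- sum(x)
  stat_of <- function(s) s / nt - (total - s) / (n - nt)
  obs <- stat_of(sum(x[tg]))
  b <- withr::with_seed(seed, {
    sum(vapply(seq_len(B), function(i)
      stat_of(sum(x[sample.int(n, nt)])), numeric(1)) >= obs)
  })
  structure(list(statistic = obs, n_perm = as.integer(B),
                 p_empirical = (b + 1) / (B + 1),
                 n_target = nt, n_gene = n),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: diff in associated-gene proportion = %.4f (targets %d / genes %d)\n",
    x$statistic, x$n_target, x$n_gene))
  cat(sprintf("empirical one-sided P = %.4g (%d permutations, add-one rule)\n",
              x$p_empirical, x$n_perm))
  invisible(x)
}
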