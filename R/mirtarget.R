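# miRNA target-site prediction in 3'UTRs: canonical seed-site caller,
# complementarity alignment scorer, nearest-neighbor duplex-stability scorer,
# k-of-n consensus, and allele-specific rescoring of SNP-containing sites.

# complement of an mRNA (DNA) base pairing a miRNA (RNA) base
.rna_comp <- c(A = "U", C = "G", G = "C", T = "A")
.dna_comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

#' Reverse complement of an RNA seed written as mRNA-sense DNA
#' @param rna character scalar over A,C,G,U.
#' @return DNA string 5'->3' complementary (antiparallel) to the input.
#' @keywords internal
.revcomp_rna_to_dna <- function(rna) {
  paste(rev(.dna_comp[strsplit(rna, "")[[1]]]), collapse = "")
}

.revcomp_dna <- function(dna) {
  paste(rev(c(A = "T", C = "G", G = "C", T = "A")[strsplit(dna, "")[[1]]]),
        collapse = "")
}

# class weights used for consensus site scoring (canonical hierarchy)
SITE_CLASS_WEIGHT <- c("8mer" = 1, "7mer-m8" = 0.75, "7mer-A1" = 0.5, "6mer" = 0.25)

#' Find canonical miRNA seed-match sites in a 3'UTR
#'
#' The seed is miRNA positions 2-8 from the 5' end. Site classes, written
#' 5'->3' on the mRNA (the site is the reverse complement of the seed, with
#' the t1 A at the site's 3' end):
#' \itemize{
#'   \item 8mer: Watson-Crick match to positions 2-8 plus an A opposite
#'     position 1;
#'   \item 7mer-m8: match to positions 2-8;
#'   \item 7mer-A1: match to positions 2-7 plus the t1 A;
#'   \item 6mer: match to positions 2-7.
#' }
#' The t1 A is required as an A in the mRNA regardless of the miRNA's
#' position-1 identity. Every occurrence is reported, overlaps included; at a
#' given seed-match locus only the longest matching class is reported (an
#' 8mer is not additionally reported as 7mer/6mer).
#'
#' @param mirna miRNA sequence, RNA alphabet, 5'->3' (character scalar or a
#'   one-row data.frame from [read_sequences()]).
#' @param utr UTR sequence, DNA alphabet, mRNA sense, 5'->3' (character
#'   scalar or one-row data.frame).
#' @return data.frame with columns mirna, transcript, site_class, utr_start,
#'   utr_end (1-based inclusive span of the paired region, including the t1 A
#'   for 8mer/7mer-A1), core_start (offset of the 6mer core).
#' @export
find_seed_sites <- function(mirna, utr) {
  mn <- .seq_in(mirna, "mirna"); un <- .seq_in(utr, "utr")
  m <- mn$seq; u <- un$seq
  L <- nchar(u)
  empty <- data.frame(mirna = character(0), transcript = character(0),
                      site_class = character(0), utr_start = integer(0),
                      utr_end = integer(0), core_start = integer(0),
                      stringsAsFactors = FALSE)
  if (L < 8L) return(empty)
  core <- .revcomp_rna_to_dna(substr(m, 2, 7))     # 6 nt, pairs miRNA 2-7
  m8 <- .dna_comp[[substr(m, 8, 8)]]               # mRNA base pairing miRNA 8
  uch <- strsplit(u, "")[[1]]
  hits <- which(vapply(seq_len(L - 5L),
                       function(p) substr(u, p, p + 5L) == core, logical(1)))
  if (!length(hits)) return(empty)
  rows <- lapply(hits, function(p) {
    has_m8 <- p > 1L && uch[p - 1L] == m8
    has_t1 <- p + 6L <= L && uch[p + 6L] == "A"
    if (has_m8 && has_t1)      c("8mer",    p - 1L, p + 6L)
    else if (has_m8)           c("7mer-m8", p - 1L, p + 5L)
    else if (has_t1)           c("7mer-A1", p,      p + 6L)
    else                       c("6mer",    p,      p + 5L)
  })
  data.frame(mirna = mn$name, transcript = un$name,
             site_class = vapply(rows, `[`, character(1), 1L),
             utr_start = as.integer(vapply(rows, `[`, character(1), 2L)),
             utr_end = as.integer(vapply(rows, `[`, character(1), 3L)),
             core_start = as.integer(hits), stringsAsFactors = FALSE)
}

.seq_in <- function(x, kind) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(name = x$name, seq = x$sequence)
  } else {
    list(name = if (kind == "mirna") "mirna" else "utr", seq = toupper(x))
  }
}

#' Complementarity alignment score between a miRNA and a UTR window
#'
#' Best antiparallel local alignment by dynamic programming with affine gaps:
#' Watson-Crick pair +5, G:U wobble +2, mismatch -3, gap open -8, gap extend
#' -2; pair scores at positions pairing miRNA 2-8 (the seed) are doubled.
#' Local alignment: the score never drops below 0 and the maximum cell is
#' returned. Parameters are complementarity-alignment defaults in the spirit
#' of classical miRNA target scanners; only their relative behavior is
#' load-bearing.
#'
#' @param mirna miRNA sequence (RNA, 5'->3').
#' @param utr_window UTR window (DNA, mRNA sense, 5'->3'), length in [6, 40].
#' @param match,wobble,mismatch,gap_open,gap_extend,seed_weight scoring
#'   parameters.
#' @return best local alignment score (>= 0).
#' @export
align_score <- function(mirna, utr_window, match = 5, wobble = 2,
                        mismatch = -3, gap_open = -8, gap_extend = -2,
                        seed_weight = 2) {
  m <- .seq_in(mirna, "mirna")$seq
  w <- .seq_in(utr_window, "utr")$seq
  lw <- nchar(w)
  if (lw < 6L || lw > 40L)
    stop("align_score: window length must lie in [6, 40]")
  mi <- strsplit(m, "")[[1]]
  # antiparallel: reverse the window so miRNA 5'->3' aligns index-wise
  wj <- rev(strsplit(w, "")[[1]])
  n <- length(mi); k <- length(wj)
  NEG <- -1e9
  M <- matrix(0, n + 1L, k + 1L)
  Ix <- matrix(NEG, n + 1L, k + 1L)  # gap in window (miRNA base unpaired)
  Iy <- matrix(NEG, n + 1L, k + 1L)  # gap in miRNA
  best <- 0
  for (i in seq_len(n)) {
    seedw <- if (i >= 2L && i <= 8L) seed_weight else 1
    for (j in seq_len(k)) {
      s <- .pair_score_tab(mi[i], wj[j], match, wobble, mismatch) * seedw
      M[i + 1L, j + 1L] <- max(0,
        M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open,
                                Ix[i, j + 1L] + gap_extend)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open,
                                Iy[i + 1L, j] + gap_extend)
      if (M[i + 1L, j + 1L] > best) best <- M[i + 1L, j + 1L]
    }
  }
  best
}

.pair_score_tab <- function(mb, ub, match, wobble, mismatch) {
  if (.rna_comp[[ub]] == mb) match
  else if ((mb == "G" && ub == "T") || (mb == "U" && ub == "G")) wobble
  else mismatch
}

# Nearest-neighbor RNA/RNA stack free energies (kcal/mol, 37C), keyed by the
# miRNA-strand dinucleotide 5'XY3' with both positions Watson-Crick paired.
# Published-style Turner values; symmetric under reverse complement.
NN_STACK <- c(
  AA = -0.93, UU = -0.93,
  AU = -1.10,
  UA = -1.33,
  AC = -2.24, GU = -2.24,
  CA = -2.11, UG = -2.11,
  AG = -2.08, CU = -2.08,
  GA = -2.35, UC = -2.35,
  CG = -2.36,
  GC = -3.42,
  GG = -3.26, CC = -3.26
)

#' Sum nearest-neighbor stack energies over a run of paired miRNA positions
#'
#' Each pair of consecutive paired positions contributes the stack energy of
#' the miRNA dinucleotide from [NN_STACK]; a stack involving a G:U wobble
#' pair is penalized by +1.0. A single pair has no stack and contributes 0.
#'
#' @param mirna_seq miRNA sequence (RNA, 5'->3').
#' @param paired_positions integer vector of miRNA positions that are paired,
#'   sorted ascending; only consecutive positions stack.
#' @param wobble logical vector parallel to `paired_positions` marking G:U
#'   pairs (default all Watson-Crick).
#' @return summed stack energy (kcal/mol-like; more negative = more stable).
#' @export
nn_stack_sum <- function(mirna_seq, paired_positions,
                         wobble = rep(FALSE, length(paired_positions))) {
  p <- as.integer(paired_positions)
  stopifnot(length(p) >= 1L, !is.unsorted(p), length(wobble) == length(p))
  if (length(p) == 1L) return(0)
  e <- 0
  for (k in seq_len(length(p) - 1L)) {
    if (p[k + 1L] != p[k] + 1L) next   # non-adjacent pairs do not stack
    din <- substr(mirna_seq, p[k], p[k + 1L])
    e <- e + NN_STACK[[din]] + (wobble[k] || wobble[k + 1L]) * 1.0
  }
  e
}

#' Duplex stability of the best seed-class site in a UTR window
#'
#' Finds the most stable canonical seed site in the window and sums
#' nearest-neighbor stack energies over its seed duplex (miRNA positions 2-7,
#' plus 8 for m8 classes); an unpaired t1 A contributes a fixed -0.3 bonus
#' for 8mer/7mer-A1 sites. Errors when the window contains no seed-class
#' site.
#'
#' @inheritParams align_score
#' @param site optionally, a single row from [find_seed_sites()] computed on
#'   the same window; skips the internal site search.
#' @return stack energy sum (kcal/mol-like, more negative = more stable).
#' @export
duplex_energy <- function(mirna, utr_window, site = NULL) {
  m <- .seq_in(mirna, "mirna")$seq
  if (is.null(site)) {
    sites <- find_seed_sites(m, .seq_in(utr_window, "utr")$seq)
    if (nrow(sites) == 0L)
      stop("duplex_energy: no seed-class site in window")
  } else sites <- site
  e <- vapply(seq_len(nrow(sites)), function(i)
    .site_energy(m, sites$site_class[i]), numeric(1))
  min(e)
}

.site_energy <- function(mirna_seq, site_class) {
  pos <- if (site_class %in% c("8mer", "7mer-m8")) 2:8 else 2:7
  e <- nn_stack_sum(mirna_seq, pos)
  if (site_class %in% c("8mer", "7mer-A1")) e <- e - 0.3
  e
}

#' Call consensus miRNA target sites with a k-of-n scorer vote
#'
#' Three scorers evaluate every canonical seed site: (1) the seed-class
#' caller (supports any canonical class; score = class weight 6mer 0.25,
#' 7mer-A1 0.5, 7mer-m8 0.75, 8mer 1), (2) the complementarity alignment
#' score over the site plus 15 nt of 5' flank (supports when >=
#' `align_cutoff`), (3) the seed duplex stability (supports when <=
#' `energy_cutoff`). A site is emitted when at least `k_min` scorers support
#' it; `k_min = 0` emits every seed-class site.
#'
#' @inheritParams find_seed_sites
#' @param k_min minimum number of supporting scorers (default 3 of 3).
#' @param align_cutoff alignment support threshold (default 55: any clean
#'   seed pairing scores >= 60 before flank contributions).
#' @param energy_cutoff duplex stability support threshold in kcal/mol
#'   (default -7: seeds with some G/C stacking pass, weak all-A/U seeds do
#'   not).
#' @return data.frame: the [find_seed_sites()] columns plus score_seed,
#'   score_align, score_energy, n_supporting.
#' @export
call_consensus <- function(mirna, utr, k_min = 3L, align_cutoff = 55,
                           energy_cutoff = -7) {
  n_scorers <- 3L
  if (k_min > n_scorers)
    stop("call_consensus: k_min exceeds the number of configured scorers")
  mn <- .seq_in(mirna, "mirna"); un <- .seq_in(utr, "utr")
  sites <- find_seed_sites(mn$seq, un$seq)
  if (nrow(sites) == 0L) return(cbind(sites, score_seed = numeric(0),
      score_align = numeric(0), score_energy = numeric(0),
      n_supporting = integer(0)))
  L <- nchar(un$seq)
  sc_seed <- SITE_CLASS_WEIGHT[sites$site_class]
  sc_align <- vapply(seq_len(nrow(sites)), function(i) {
    a <- max(1L, sites$utr_start[i] - 15L)
    b <- min(L, sites$utr_end[i])
    if (b - a + 1L > 40L) a <- b - 39L
    align_score(mn$seq, substr(un$seq, a, b))
  }, numeric(1))
  sc_energy <- vapply(seq_len(nrow(sites)), function(i)
    .site_energy(mn$seq, sites$site_class[i]), numeric(1))
  n_sup <- 1L + (sc_align >= align_cutoff) + (sc_energy <= energy_cutoff)
  out <- cbind(sites, score_seed = unname(sc_seed), score_align = sc_align,
               score_energy = sc_energy, n_supporting = as.integer(n_sup))
  out[out$n_supporting >= k_min, , drop = FALSE]
}

.consensus_site_score <- function(calls) {
  # normalized per-site score: class weight + alignment/75 + stability/10
  if (nrow(calls) == 0L) return(0)
  sum(calls$score_seed + calls$score_align / 75 +
        pmax(0, -calls$score_energy) / 10)
}

#' Allele-specific change in predicted miRNA binding at a SNP
#'
#' The consensus site score (sum over called sites overlapping the SNP of
#' class weight + alignment score / 75 + max(0, -energy) / 10) is computed on
#' the reference-allele UTR and on the alternative-allele-substituted UTR.
#' `delta = score_alt - score_ref`; `delta < 0` (weakened binding) predicts
#' de-repression, i.e. expression direction "up" for the alternative allele.
#' SNPs overlapping no site under either allele give delta 0, direction
#' "none". Swapping the ref/alt labels flips delta's sign exactly.
#'
#' @inheritParams find_seed_sites
#' @param ref_allele,alt_allele single DNA bases (UTR/mRNA-sense
#'   orientation); `ref_allele` must match the UTR at `utr_offset`.
#' @param utr_offset 1-based UTR position of the SNP.
#' @param k_min consensus threshold used when scoring overlapping sites
#'   (default 1: any canonical site change is captured).
#' @inheritParams call_consensus
#' @return list of class `allele_delta`: mirna, transcript, utr_offset,
#'   ref_allele, alt_allele, score_ref, score_alt, delta,
#'   predicted_expression_direction.
#' @export
allele_delta <- function(mirna, utr, ref_allele, alt_allele, utr_offset,
                         k_min = 1L, align_cutoff = 55, energy_cutoff = -7) {
  mn <- .seq_in(mirna, "mirna"); un <- .seq_in(utr, "utr")
  u <- un$seq
  stopifnot(utr_offset >= 1L, utr_offset <= nchar(u))
  if (substr(u, utr_offset, utr_offset) != ref_allele)
    stop("allele_delta: ref allele '", ref_allele,
         "' does not match UTR base '",
         substr(u, utr_offset, utr_offset), "' at offset ", utr_offset)
  u_alt <- u
  substr(u_alt, utr_offset, utr_offset) <- alt_allele
  score_for <- function(seq) {
    calls <- call_consensus(mn$seq, seq, k_min = k_min,
                            align_cutoff = align_cutoff,
                            energy_cutoff = energy_cutoff)
    ov <- calls[calls$utr_start <= utr_offset & calls$utr_end >= utr_offset, ,
                drop = FALSE]
    .consensus_site_score(ov)
  }
  score_ref <- score_for(u)
  score_alt <- score_for(u_alt)
  delta <- score_alt - score_ref
  structure(list(
    mirna = mn$name, transcript = un$name, utr_offset = as.integer(utr_offset),
    ref_allele = ref_allele, alt_allele = alt_allele,
    score_ref = score_ref, score_alt = score_alt, delta = delta,
    predicted_expression_direction =
      if (delta < 0) "up" else if (delta > 0) "down" else "none"),
    class = "allele_delta")
}

#' Project a genomic variant into UTR coordinates
#'
#' UTR sequences are stored mRNA-sense; for minus-strand transcripts the
#' genomic anchor is the smallest genomic coordinate and alleles are
#' reverse-complemented into mRNA orientation.
#'
#' @param utr_row one row of a UTR table from [read_sequences()].
#' @param chrom,pos,ref,alt the variant (genomic, plus-strand alleles).
#' @return list(offset, ref, alt) in UTR coordinates/orientation, or NULL if
#'   the variant does not fall inside the UTR.
#' @export
project_variant_to_utr <- function(utr_row, chrom, pos, ref, alt) {
  len <- nchar(utr_row$sequence)
  g0 <- utr_row$utr_genomic_start
  if (!identical(as.character(chrom), utr_row$chrom)) return(NULL)
  if (pos < g0 || pos > g0 + len - 1L) return(NULL)
  if (utr_row$strand == "+") {
    list(offset = pos - g0 + 1L, ref = ref, alt = alt)
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    list(offset = g0 + len - pos, ref = comp[[ref]], alt = comp[[alt]])
  }
}

#' Annotate LD proxies with allele-specific miRNA binding predictions
#'
#' The machine-readable twin of a GWAS-SNP/proxy-SNP/miRNA/transcript
#' annotation table: one row per (index SNP, proxy SNP, miRNA, transcript)
#' where the proxy falls inside the transcript's 3'UTR and changes the
#' consensus site score (rows with delta = 0 are dropped).
#'
#' @param proxies data.frame from [find_proxies()].
#' @param utrs UTR table from [read_sequences()].
#' @param mirnas miRNA table from [read_sequences()].
#' @param k_min consensus threshold passed to [allele_delta()].
#' @inheritParams call_consensus
#' @return data.frame with columns gwas_snp, site_snp, chrom, pos,
#'   distance_bp, alleles, r2, mirna, gene, transcript, delta, direction.
#' @export
map_snps_to_sites <- function(proxies, utrs, mirnas, k_min = 1L,
                              align_cutoff = 55, energy_cutoff = -7) {
  out <- list()
  for (i in seq_len(nrow(proxies))) {
    px <- proxies[i, ]
    for (t in seq_len(nrow(utrs))) {
      utr_row <- utrs[t, ]
      pr <- project_variant_to_utr(utr_row, px$chrom, px$pos_proxy,
                                   px$ref, px$alt)
      if (is.null(pr)) next
      for (mi in seq_len(nrow(mirnas))) {
        ad <- tryCatch(
          allele_delta(mirnas[mi, ], utr_row, pr$ref, pr$alt, pr$offset,
                       k_min = k_min, align_cutoff = align_cutoff,
                       energy_cutoff = energy_cutoff),
          error = function(e) {
            .msg("map_snps_to_sites: skipping ", px$proxy_id, " x ",
                 utr_row$transcript_id, ": ", conditionMessage(e))
            NULL
          })
        if (is.null(ad) || ad$delta == 0) next
        out[[length(out) + 1L]] <- data.frame(
          gwas_snp = px$index_id, site_snp = px$proxy_id,
          chrom = px$chrom, pos = px$pos_proxy,
          distance_bp = px$distance_bp,
          alleles = paste0(px$ref, "/", px$alt), r2 = px$r2,
          mirna = mirnas$name[mi], gene = utr_row$gene_symbol,
          transcript = utr_row$transcript_id,
          delta = ad$delta,
          direction = ad$predicted_expression_direction,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gwas_snp = character(0), site_snp = character(0),
                      chrom = character(0), pos = integer(0),
                      distance_bp = integer(0), alleles = character(0),
                      r2 = numeric(0), mirna = character(0),
                      gene = character(0), transcript = character(0),
                      delta = numeric(0), direction = character(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}
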