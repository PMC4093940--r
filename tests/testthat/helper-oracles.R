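# Independent oracles used across the suite. These deliberately avoid the
# package's own helpers: string/table computations from first principles.

# brute-force seed-site enumeration: build each class's site text from the
# seed and test every window; at one seed-match core keep only the longest
# matching class (an 8mer is not additionally a 7mer/6mer).
oracle_seed_sites <- function(mirna, utr) {
  if (nchar(utr) < 8L) return(data.frame(site_class = character(0),
                                         utr_start = integer(0),
                                         utr_end = integer(0)))
  comp <- c(A = "T", C = "G", G = "C", U = "A")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  core6 <- rc(substr(mirna, 2, 7))
  site7 <- rc(substr(mirna, 2, 8))
  defs <- list("8mer" = paste0(site7, "A"), "7mer-m8" = site7,
               "7mer-A1" = paste0(core6, "A"), "6mer" = core6)
  core_off <- c("8mer" = 1L, "7mer-m8" = 1L, "7mer-A1" = 0L, "6mer" = 0L)
  rank <- c("8mer" = 4L, "7mer-m8" = 3L, "7mer-A1" = 2L, "6mer" = 1L)
  hits <- list()
  for (cls in names(defs)) {
    pat <- defs[[cls]]; L <- nchar(pat)
    if (nchar(utr) < L) next
    for (s in seq_len(nchar(utr) - L + 1L))
      if (substr(utr, s, s + L - 1L) == pat)
        hits[[length(hits) + 1L]] <- data.frame(
          site_class = cls, utr_start = s, utr_end = s + L - 1L,
          core = s + core_off[[cls]], rank = rank[[cls]],
          stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(data.frame(site_class = character(0),
                                       utr_start = integer(0),
                                       utr_end = integer(0)))
  h <- do.call(rbind, hits)
  keep <- unlist(lapply(split(seq_len(nrow(h)), h$core), function(idx) {
    idx[which.max(h$rank[idx])]
  }), use.names = FALSE)
  h <- h[keep, c("site_class", "utr_start", "utr_end", "core")]
  h <- h[order(h$core), ]
  rownames(h) <- NULL
  h
}

# direct 2x2 haplotype-table r^2
oracle_r2 <- function(a, b) {
  n <- length(a)
  p11 <- sum(a == 1 & b == 1) / n
  pA <- sum(a) / n; pB <- sum(b) / n
  D <- p11 - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

rand_rna <- function(len = sample(18:24, 1)) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a strong-pairing miRNA (G/C-rich seed) used where consensus support from
# the stability scorer is required by construction
strong_mirna <- function() "AGCGGCCAUGCUAAGCUAGCUA"   # seed 2-8 = GCGGCCA
# an all-A/U seed: alignment supports it, seed stability does not
weak_mirna <- function() "AUAUAUAUGGCCAUGCAUGCA"       # seed 2-8 = UAUAUAU

# mRNA-sense site text for a class, built independently of package internals
.site_seq_for_test <- function(m, cls) {
  comp <- c(A = "T", C = "G", G = "C", U = "A")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  switch(cls,
         "8mer"    = paste0(rc(substr(m, 2, 8)), "A"),
         "7mer-m8" = rc(substr(m, 2, 8)),
         "7mer-A1" = paste0(rc(substr(m, 2, 7)), "A"),
         "6mer"    = rc(substr(m, 2, 7)))
}

make_gm <- function(dosages, chrom = "1", pos = NULL, ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  genotype_matrix(sprintf("s%03d", seq_len(nrow(dosages))),
                  variant_table(chrom, pos, ids, rep("A", m), rep("G", m)),
                  dosages)
}
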