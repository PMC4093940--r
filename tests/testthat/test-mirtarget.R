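# mirtarget: seed-site caller vs brute-force oracle, alignment and duplex
# scorers, consensus, allele-specific rescoring

test_that("find_seed_sites: worked examples and class boundaries", {
  m <- "AUGGCUAAGCUAGCUAGCUA"          # seed 2-8 = UGGCUAA
  s <- find_seed_sites(m, "GGGTTAGCCAAGGG")
  expect_identical(s$site_class, "8mer")
  expect_identical(s$utr_start, 4L)
  expect_identical(s$utr_end, 11L)
  # non-A at t1 with the m8 match: 7mer-m8, not 8mer
  s2 <- find_seed_sites(m, "GGGTTAGCCAGGGG")
  expect_identical(s2$site_class, "7mer-m8")
  expect_identical(s2$utr_start, 4L)
  expect_identical(s2$utr_end, 10L)
  # no complement at all
  expect_identical(nrow(find_seed_sites(m, strrep("A", 30))), 0L)
  # UTR shorter than 8: empty
  expect_identical(nrow(find_seed_sites(m, "TTAGCC")), 0L)
})

test_that("find_seed_sites equals brute-force window enumeration", {
  set.seed(40)
  for (i in 1:300) {
    m <- rand_rna()
    u <- rand_dna(sample(8:60, 1))
    got <- find_seed_sites(m, u)
    exp <- oracle_seed_sites(m, u)
    expect_identical(nrow(got), nrow(exp))
    if (nrow(got)) {
      got <- got[order(got$core_start), ]
      expect_identical(got$site_class, exp$site_class)
      expect_identical(got$utr_start, exp$utr_start)
      expect_identical(got$utr_end, exp$utr_end)
    }
  }
})

test_that("emitted sites re-validate their class definition", {
  set.seed(41)
  comp <- c(A = "T", C = "G", G = "C", U = "A")
  # one guaranteed site plus random backgrounds
  m0 <- strong_mirna()
  u0 <- paste0(rand_dna(20), .site_seq_for_test(m0, "8mer"), rand_dna(20))
  s0 <- find_seed_sites(m0, u0)
  expect_gte(nrow(s0), 1L)
  for (i in 1:50) {
    m <- if (i == 1) m0 else rand_rna()
    u <- if (i == 1) u0 else rand_dna(60)
    s <- find_seed_sites(m, u)
    for (k in seq_len(nrow(s))) {
      rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
      expected_text <- switch(s$site_class[k],
        "8mer"    = paste0(rc(substr(m, 2, 8)), "A"),
        "7mer-m8" = rc(substr(m, 2, 8)),
        "7mer-A1" = paste0(rc(substr(m, 2, 7)), "A"),
        "6mer"    = rc(substr(m, 2, 7)))
      expect_identical(substr(u, s$utr_start[k], s$utr_end[k]), expected_text)
    }
  }
})

test_that("align_score: hand-summed seed weighting, floor, bounds", {
  m <- "AUGGCUAAGCUAGCUAGCUA"
  # fully WC-paired ungapped 8-nt window covering miRNA 1-8:
  # revcomp of AUGGCUAA is TTAGCCAT; position 1 scores 5, 2-8 score 10 each
  expect_equal(align_score(m, "TTAGCCAT"), 75)
  # zero complementarity floors at 0
  expect_equal(align_score("AAAAAAAAAAAAAAAAAAAA", "AAAAAA"), 0)
  expect_error(align_score(m, "ACGTA"), "window length")
  expect_error(align_score(m, rand_dna(41)), "window length")
  # more pairing never hurts: score of a window containing a full 8mer site
  # is at least the seed contribution
  expect_gte(align_score(strong_mirna(),
                         paste0("ACGT", .site_seq_for_test(strong_mirna(), "8mer"))),
             70)
})

test_that("duplex stability: no-stack base case, manual table walk, monotonicity", {
  # a single pair has no stacking neighbors
  expect_equal(nn_stack_sum("AGCGGCCAUGCUAAGCUAGCUA", 5L), 0)
  # non-adjacent pairs do not stack
  expect_equal(nn_stack_sum("AGCGGCCAUGCUAAGCUAGCUA", c(2L, 4L)), 0)
  # manual walk of the 8mer seed duplex of AGCGGCCA...: dinucleotides over
  # positions 2-8 are GC, CG, GG, GC, CC, CA
  manual <- -3.42 + -2.36 + -3.26 + -3.42 + -3.26 + -2.11
  expect_equal(nn_stack_sum(strong_mirna(), 2:8), manual)
  u8 <- .site_seq_for_test(strong_mirna(), "8mer")
  expect_equal(duplex_energy(strong_mirna(), paste0("GG", u8, "GG")),
               manual - 0.3)   # t1 A bonus for the 8mer
  # wobble stacks are penalized by +1 each
  expect_equal(nn_stack_sum(strong_mirna(), 2:3, wobble = c(TRUE, FALSE)),
               -3.42 + 1)
  expect_error(duplex_energy(strong_mirna(), "TTTTTTTTTT"), "no seed-class")
  # extending a run of WC pairs never makes the energy less negative
  set.seed(42)
  for (i in 1:30) {
    m <- rand_rna()
    k <- sample(3:6, 1)
    e_short <- nn_stack_sum(m, 2:k)
    e_long <- nn_stack_sum(m, 2:(k + 1))
    expect_lte(e_long, e_short)
  }
})

test_that("call_consensus: k-of-n vote, cutoff straddling, monotone in k_min", {
  u8 <- paste0("CCGG", .site_seq_for_test(strong_mirna(), "8mer"), "AACC")
  calls <- call_consensus(strong_mirna(), u8, k_min = 3)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$n_supporting, 3L)
  # weak all-A/U seed: seed class + alignment support it, stability does not
  u6 <- paste0("CCGG", .site_seq_for_test(weak_mirna(), "6mer"), "CCGG")
  marginal <- call_consensus(weak_mirna(), u6, k_min = 0)
  expect_identical(marginal$n_supporting, 2L)
  expect_identical(nrow(call_consensus(weak_mirna(), u6, k_min = 3)), 0L)
  # k_min = 0 emits every seed-class site
  expect_identical(nrow(call_consensus(weak_mirna(), u6, k_min = 0)), 1L)
  expect_error(call_consensus(strong_mirna(), u8, k_min = 4), "k_min")
  # raising k_min never adds calls
  set.seed(43)
  for (i in 1:20) {
    m <- rand_rna(); u <- rand_dna(60)
    n_by_k <- vapply(0:3, function(k)
      nrow(call_consensus(m, u, k_min = k)), integer(1))
    expect_true(all(diff(n_by_k) <= 0))
  }
})

test_that("allele_delta: direction convention and exact antisymmetry", {
  m <- strong_mirna()
  site <- .site_seq_for_test(m, "8mer")
  u <- paste0("CCGGAACC", site, "TTGGAACC")
  off <- 10L                       # inside the seed-pairing region
  ref <- substr(u, off, off)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  ad <- allele_delta(m, u, ref, alt, off)
  expect_lt(ad$score_alt, ad$score_ref)
  expect_lt(ad$delta, 0)
  expect_identical(ad$predicted_expression_direction, "up")
  # swapping ref/alt labels flips delta exactly
  u_alt <- u; substr(u_alt, off, off) <- alt
  ad_rev <- allele_delta(m, u_alt, alt, ref, off)
  expect_equal(ad_rev$delta, -ad$delta)
  # SNP far from any site: delta 0, direction none
  ad0 <- allele_delta(m, u, substr(u, 2, 2), "A", 2L)
  expect_equal(ad0$delta, 0)
  expect_identical(ad0$predicted_expression_direction, "none")
  # ref mismatch is a data-integrity error
  expect_error(allele_delta(m, u, setdiff(c("A", "C"), ref)[1], "G", off),
               "does not match")
})

test_that("variant projection into UTR offsets handles both strands", {
  utr_p <- data.frame(name = "T1", kind = "utr", sequence = "ACGTACGTAC",
                      transcript_id = "T1", gene_symbol = "G1", chrom = "12",
                      strand = "+", utr_genomic_start = 1000L,
                      stringsAsFactors = FALSE)
  pr <- project_variant_to_utr(utr_p, "12", 1003L, "T", "C")
  expect_equal(pr$offset, 4L)
  expect_identical(pr$ref, "T")
  expect_null(project_variant_to_utr(utr_p, "12", 2000L, "A", "G"))
  expect_null(project_variant_to_utr(utr_p, "11", 1003L, "A", "G"))
  # minus strand: offset counts from the genomic end; alleles complemented
  utr_m <- utr_p; utr_m$strand <- "-"
  # genomic span 1000-1009; the genomic end maps to mRNA offset 1
  pr_m <- project_variant_to_utr(utr_m, "12", 1008L, "G", "A")
  expect_equal(pr_m$offset, 2L)     # second base of the mRNA-sense sequence
  expect_identical(pr_m$ref, "C")   # complement of the plus-strand allele
  expect_identical(pr_m$alt, "T")
  expect_identical(substr(utr_m$sequence, 2, 2), "C")
})

test_that("map_snps_to_sites reconstructs the proxy-in-seed-site topology", {
  m <- strong_mirna()
  site <- .site_seq_for_test(m, "8mer")
  anchor <- 2061900L
  u_seq <- paste0(strrep("CT", 10), site, strrep("GA", 10))
  site_start <- 21L
  utrs <- data.frame(name = "TX1", kind = "utr", sequence = u_seq,
                     transcript_id = "TX1", gene_symbol = "GENE1",
                     chrom = "12", strand = "+",
                     utr_genomic_start = anchor, stringsAsFactors = FALSE)
  snp_off <- site_start + 3L        # inside the seed-pairing core
  snp_pos <- anchor + snp_off - 1L
  ref <- substr(u_seq, snp_off, snp_off)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mirnas <- data.frame(name = "mir-x", kind = "mirna", sequence = m,
                       stringsAsFactors = FALSE)
  proxies <- data.frame(index_id = "idx1", proxy_id = "prox1", chrom = "12",
                        pos_index = snp_pos - 42188L, pos_proxy = snp_pos,
                        ref = ref, alt = alt, r2 = 1,
                        distance_bp = 42188L, stringsAsFactors = FALSE)
  tab <- map_snps_to_sites(proxies, utrs, mirnas)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$transcript, "TX1")
  expect_equal(tab$r2, 1)
  expect_identical(tab$distance_bp, 42188L)
  expect_identical(tab$direction, "up")
  # a proxy outside every UTR yields no row
  proxies2 <- proxies; proxies2$pos_proxy <- anchor - 100L
  expect_identical(nrow(map_snps_to_sites(proxies2, utrs, mirnas)), 0L)
  # SNP inside a UTR with no site for the miRNA yields no row
  utrs3 <- utrs; utrs3$sequence <- strrep("CT", 30)
  expect_identical(nrow(map_snps_to_sites(proxies, utrs3, mirnas)), 0L)
})
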