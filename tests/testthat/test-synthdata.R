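# synthdata: generators are pure functions of seed; planted structure is
# recoverable; LD block mosaic produces the r^2 regimes downstream stages need

test_that("gen_panel: determinism, polymorphism, block r^2 structure", {
  p1 <- gen_panel(40, 30, block_len = 10, n_founders = 4,
                  mutation_rate = 0.02, seed = 3)
  p2 <- gen_panel(40, 30, block_len = 10, n_founders = 4,
                  mutation_rate = 0.02, seed = 3)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$variants, p2$variants)
  # every variant polymorphic
  expect_true(all(apply(p1$haplotypes, 2, var) > 0))
  # mutation_rate 0, one block, 2 founders: every within-block pair r^2 = 1
  p <- gen_panel(30, 8, block_len = 8, n_founders = 2, mutation_rate = 0,
                 seed = 4)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(compute_r2(p$haplotypes[, i], p$haplotypes[, j],
                            "haplotype"), 1)
  # between-block r^2 much lower than within-block at many founders
  pb <- gen_panel(200, 40, block_len = 20, n_founders = 2,
                  mutation_rate = 0, seed = 5)
  within <- mean(vapply(2:20, function(j)
    compute_r2(pb$haplotypes[, 1], pb$haplotypes[, j], "haplotype"),
    numeric(1)))
  between <- mean(vapply(21:40, function(j)
    compute_r2(pb$haplotypes[, 1], pb$haplotypes[, j], "haplotype"),
    numeric(1)))
  expect_equal(within, 1)
  expect_lt(between, 0.2)
})

test_that("gen_cohort: dosages sum two haplotypes; frequencies track panel", {
  # degenerate all-ones panel: every dosage is 2
  panel <- structure(list(
    haplotypes = matrix(1L, 10, 3),
    variants = variant_table("1", c(100, 200, 300), c("a", "b", "c"),
                             rep("A", 3), rep("G", 3)),
    block_starts = 1L), class = "haplotype_panel")
  gm <- gen_cohort(panel, 5, seed = 1)
  expect_true(all(gm$dosages == 2))
  # frequency check within binomial error
  p <- gen_panel(100, 10, block_len = 5, seed = 6)
  gm <- gen_cohort(p, 1000, seed = 7)
  f_panel <- colMeans(p$haplotypes)
  f_cohort <- colMeans(gm$dosages) / 2
  se <- sqrt(f_panel * (1 - f_panel) / (2 * 1000))
  expect_true(all(abs(f_cohort - f_panel) < 4 * se + 1e-9))
  expect_identical(gen_cohort(p, 50, seed = 8)$dosages,
                   gen_cohort(p, 50, seed = 8)$dosages)
})

test_that("gen_phenotype: planted model, degenerate cases, determinism", {
  p <- gen_panel(40, 6, block_len = 3, seed = 9)
  gm <- gen_cohort(p, 30, seed = 10)
  # all effects zero, zero noise: constant phenotype
  ph0 <- gen_phenotype(gm, noise_sd = 0, seed = 11)
  expect_equal(var(ph0$pheno$trait), 0)
  expect_error(gen_phenotype(gm, noise_sd = -1), "noise_sd")
  expect_error(gen_phenotype(gm, effects = c(nosuch = 1)), "nosuch")
  ph1 <- gen_phenotype(gm, effects = setNames(0.5, "snp0002"), seed = 12)
  ph2 <- gen_phenotype(gm, effects = setNames(0.5, "snp0002"), seed = 12)
  expect_identical(ph1$pheno, ph2$pheno)
  # covariates within their stated ranges
  expect_true(all(ph1$pheno$age >= 60 & ph1$pheno$age <= 80))
  expect_true(all(ph1$pheno$sex %in% 0:1))
  expect_true(all(ph1$pheno$education >= 8 & ph1$pheno$education <= 20))
})

test_that("gen_targetome: planted sites recovered, site_rate 0 clean", {
  mirnas <- data.frame(name = c("m1", "m2"), kind = "mirna",
                       sequence = c(strong_mirna(), weak_mirna()),
                       stringsAsFactors = FALSE)
  tg0 <- gen_targetome(mirnas, 5, site_rate = 0, seed = 13)
  expect_null(tg0$truth$sites)
  for (i in seq_len(nrow(tg0$utrs)))
    for (j in seq_len(nrow(mirnas)))
      expect_identical(nrow(find_seed_sites(mirnas[j, ], tg0$utrs[i, ])), 0L)
  tg <- gen_targetome(mirnas, 20, site_rate = 0.8, snp_in_site_rate = 0.5,
                      seed = 14)
  # every planted site is recovered at the planted offset and class
  for (i in seq_len(nrow(tg$truth$sites))) {
    s <- tg$truth$sites[i, ]
    utr <- tg$utrs[tg$utrs$transcript_id == s$transcript, ]
    mir <- mirnas[mirnas$name == s$mirna, ]
    found <- find_seed_sites(mir, utr)
    expect_identical(nrow(found), 1L)
    expect_identical(found$site_class, s$site_class)
    expect_identical(found$utr_start, s$utr_start)
  }
  # planted SNP ids resolve and their ref allele matches the UTR
  if (!is.null(tg$truth$snps)) for (i in seq_len(nrow(tg$truth$snps))) {
    sn <- tg$truth$snps[i, ]
    utr <- tg$utrs[tg$utrs$transcript_id == sn$transcript, ]
    expect_identical(substr(utr$sequence, sn$utr_offset, sn$utr_offset),
                     sn$ref)
    expect_true(sn$id %in% tg$variants$id)
  }
  expect_identical(gen_targetome(mirnas, 6, seed = 15)$utrs,
                   gen_targetome(mirnas, 6, seed = 15)$utrs)
})

test_that("gen_expression: planted effect, outliers, determinism", {
  d <- rep(0:2, each = 10)
  e0 <- gen_expression(d, beta_per_allele = 0, noise_sd = 0,
                       outlier_frac = 0, seed = 16)
  expect_equal(var(e0$expression), 0)
  e1 <- gen_expression(d, outlier_frac = 0.1, outlier_shift = 1000, seed = 17)
  expect_identical(length(e1$truth$outlier_idx), 3L)  # floor(0.1 * 30)
  expect_identical(e1$expression,
                   gen_expression(d, outlier_frac = 0.1,
                                  outlier_shift = 1000, seed = 17)$expression)
  expect_error(gen_expression(d, outlier_frac = 1), "outlier_frac")
})

test_that("gen_plate: noise-free ratios are exact; determinism", {
  pl0 <- gen_plate(n_experiments = 3, allele_effect = 0, cv = 0, seed = 18)
  r <- normalize_to_control(pl0$data)
  expect_equal(r$ratio[r$allele == "alt"], r$ratio[r$allele == "ref"])
  pl <- gen_plate(n_experiments = 3, knockdown_ref = 0.585, cv = 0, seed = 19)
  expect_equal(unique(normalize_to_control(pl$data)$ratio[
    normalize_to_control(pl$data)$allele == "ref"]), 0.585)
  expect_identical(gen_plate(seed = 20)$data, gen_plate(seed = 20)$data)
})
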