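# Synthetic inputs with the statistical structure each pipeline stage
# assumes, plus ground-truth tables for parameter-recovery tests. Every
# generator is a pure function of its parameters and seed.

#' Generate a phased haplotype panel with block LD structure
#'
#' LD is modeled as a founder-copying block mosaic: within each block every
#' haplotype copies one of the block's founder haplotypes (with per-site
#' mutation at `mutation_rate`); founder choice is re-randomized between
#' blocks. This produces high within-block and low between-block r2 — the
#' two regimes the proxy stage needs — and is exactly analyzable (with
#' `mutation_rate = 0` and 2 founders, all within-block pairs have r2 = 1).
#'
#' @param n_hap number of haplotypes (even).
#' @param n_var number of variants.
#' @param block_len variants per LD block.
#' @param n_founders founder haplotypes per block (>= 2).
#' @param mutation_rate per-site copy-error probability.
#' @param seed RNG seed; the generator is a pure function of it.
#' @param chrom chromosome label.
#' @param positions optional integer vector of 1-based positions (length
#'   `n_var`); default evenly spaced `pos_spacing` apart from `pos_start`.
#' @param pos_start,pos_spacing used when `positions` is NULL.
#' @return object of class `haplotype_panel`: list(haplotypes
#'   (n_hap x n_var 0/1 matrix), variants, block_starts).
#' @export
gen_panel <- function(n_hap, n_var, block_len = 20L, n_founders = 4L,
                      mutation_rate = 0.01, seed = 1L, chrom = "1",
                      positions = NULL, pos_start = 100000L,
                      pos_spacing = 1000L) {
  stopifnot(n_hap %% 2L == 0L, n_founders >= 2L, n_hap >= 2L)
  if (is.null(positions))
    positions <- pos_start + (seq_len(n_var) - 1L) * pos_spacing
  stopifnot(length(positions) == n_var)
  withr::with_seed(seed, {
    block_starts <- seq(1L, n_var, by = block_len)
    H <- matrix(0L, n_hap, n_var)
    for (bs in block_starts) {
      be <- min(bs + block_len - 1L, n_var)
      len <- be - bs + 1L
      # founder assignment; force >= 2 distinct founders in the panel
      for (try in 1:50) {
        assign <- sample.int(n_founders, n_hap, replace = TRUE)
        if (length(unique(assign)) >= 2L) break
      }
      founders <- matrix(0L, n_founders, len)
      for (j in seq_len(len)) {
        ok <- FALSE
        for (try in 1:100) {
          f <- rbinom(n_founders, 1L, runif(1, 0.2, 0.8))
          col <- f[assign]
          if (mutation_rate > 0) {
            flip <- rbinom(n_hap, 1L, mutation_rate) == 1L
            col[flip] <- 1L - col[flip]
          }
          if (var(col) > 0) { founders[, j] <- f; H[, bs + j - 1L] <- col; ok <- TRUE; break }
        }
        if (!ok) stop("gen_panel: could not generate polymorphic variant ",
                      bs + j - 1L, " after 100 retries")
      }
    }
    ids <- sprintf("snp%04d", seq_len(n_var))
    ra <- t(vapply(seq_len(n_var), function(i) sample(DNA_BASES, 2L),
                   character(2)))
    structure(list(haplotypes = H,
                   variants = variant_table(chrom, positions, ids,
                                            ra[, 1], ra[, 2]),
                   block_starts = block_starts),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d variants, %d block(s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), length(x$block_starts)))
  invisible(x)
}

#' Draw a diploid cohort from a haplotype panel
#'
#' Each individual is the sum of two haplotypes drawn with replacement;
#' dosages are integers in {0, 1, 2}.
#'
#' @param panel [gen_panel()] output.
#' @param n_ind number of individuals.
#' @param seed RNG seed.
#' @return [genotype_matrix()].
#' @export
gen_cohort <- function(panel, n_ind, seed = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"), n_ind >= 1L)
  withr::with_seed(seed, {
    nh <- nrow(panel$haplotypes)
    h1 <- sample.int(nh, n_ind, replace = TRUE)
    h2 <- sample.int(nh, n_ind, replace = TRUE)
    dos <- panel$haplotypes[h1, , drop = FALSE] +
      panel$haplotypes[h2, , drop = FALSE]
    genotype_matrix(sprintf("ind%04d", seq_len(n_ind)), panel$variants, dos)
  })
}

#' Simulate a quantitative phenotype with planted additive SNP effects
#'
#' `y = sum(beta_v * dosage_v) + covariate effects + Normal(0, noise_sd)`.
#' Covariates mimic an aging cohort: age ~ Uniform(60, 80), sex ~
#' Bernoulli(0.5) coded 0/1, education ~ Normal(13, 3) truncated to
#' `[8, 20]` years.
#'
#' @param gm [genotype_matrix()].
#' @param effects named numeric vector, variant id -> beta (trait units per
#'   alt allele); all names must be present in `gm`.
#' @param covar_effects named numeric vector with entries age, sex,
#'   education (default all 0).
#' @param noise_sd residual SD (>= 0).
#' @param seed RNG seed.
#' @param trait trait column name.
#' @return list(pheno = data.frame(sample_id, <trait>, age, sex, education),
#'   truth = list(effects, covar_effects, noise_sd)).
#' @export
gen_phenotype <- function(gm, effects = numeric(0),
                          covar_effects = c(age = 0, sex = 0, education = 0),
                          noise_sd = 1, seed = 1L, trait = "trait") {
  if (noise_sd < 0) stop("gen_phenotype: noise_sd must be >= 0")
  miss <- setdiff(names(effects), gm$variants$id)
  if (length(miss)) stop("gen_phenotype: effect variants not in genotypes: ",
                         paste(miss, collapse = ", "))
  ce <- c(age = 0, sex = 0, education = 0)
  ce[names(covar_effects)] <- covar_effects
  withr::with_seed(seed, {
    n <- length(gm$sample_ids)
    age <- runif(n, 60, 80)
    sex <- rbinom(n, 1L, 0.5)
    edu <- pmin(pmax(rnorm(n, 13, 3), 8), 20)
    g_term <- if (length(effects))
      as.numeric(gm$dosages[, names(effects), drop = FALSE] %*% effects)
    else 0
    y <- g_term + ce[["age"]] * age + ce[["sex"]] * sex +
      ce[["education"]] * edu + rnorm(n, 0, noise_sd)
    pheno <- data.frame(sample_id = gm$sample_ids, y = y, age = age,
                        sex = sex, education = edu, stringsAsFactors = FALSE)
    names(pheno)[2] <- trait
    list(pheno = pheno,
         truth = list(effects = effects, covar_effects = ce,
                      noise_sd = noise_sd))
  })
}

#' Simulate a 3'UTR targetome with planted seed sites and site-breaking SNPs
#'
#' Random-background UTRs; with probability `site_rate` a canonical site
#' (class drawn uniformly from 8mer, 7mer-m8, 7mer-A1, 6mer) for a random
#' miRNA is planted at a random offset; with probability `snp_in_site_rate` a
#' SNP is planted inside a planted site's seed-pairing region with the ref
#' allele matching the site and the alt allele breaking complementarity.
#' Backgrounds are rejection-sampled so that, after planting, the only seed
#' matches present (for any supplied miRNA) are the planted ones, and the
#' alt-substituted sequence creates no new site.
#'
#' @param mirnas miRNA table from [read_sequences()] (columns name,
#'   sequence).
#' @param n_transcripts number of UTRs.
#' @param site_rate per-transcript probability of a planted site.
#' @param snp_in_site_rate probability a planted site carries a SNP.
#' @param utr_len UTR length (>= 30).
#' @param seed RNG seed.
#' @param chrom chromosome label; UTRs are placed plus-strand, spaced
#'   `spacing_bp` apart from `start_bp`.
#' @param start_bp,spacing_bp genomic layout of the UTRs.
#' @param max_tries rejection budget per transcript.
#' @return list(utrs (UTR table as [read_sequences()]), variants (SNP
#'   [variant_table()] in genomic coordinates), truth = list(sites, snps)).
#' @export
gen_targetome <- function(mirnas, n_transcripts, site_rate = 0.7,
                          snp_in_site_rate = 0.5, utr_len = 300L, seed = 1L,
                          chrom = "12", start_bp = 2000000L,
                          spacing_bp = 10000L, max_tries = 200L) {
  stopifnot(utr_len >= 30L)
  withr::with_seed(seed, {
    sites <- list(); snps <- list(); utr_rows <- list(); vars <- list()
    for (t in seq_len(n_transcripts)) {
      tid <- sprintf("TX%04d", t)
      gene <- sprintf("GENE%03d", t)
      anchor <- start_bp + (t - 1L) * spacing_bp
      plant <- runif(1) < site_rate
      mi <- if (plant) sample.int(nrow(mirnas), 1L) else NA_integer_
      cls <- if (plant) sample(names(SITE_CLASS_WEIGHT), 1L) else NA_character_
      done <- FALSE
      for (try in seq_len(max_tries)) {
        bg <- paste(sample(DNA_BASES, utr_len, replace = TRUE), collapse = "")
        if (!plant) {
          if (.any_site(mirnas, bg)) next
          utr_rows[[t]] <- .utr_row(tid, gene, bg, chrom, anchor)
          done <- TRUE; break
        }
        site_seq <- .site_sequence(mirnas$sequence[mi], cls)
        slen <- nchar(site_seq)
        off <- sample.int(utr_len - slen + 1L, 1L)
        seq <- bg
        substr(seq, off, off + slen - 1L) <- site_seq
        found <- find_seed_sites(mirnas$sequence[mi], seq)
        ok <- nrow(found) == 1L && found$site_class == cls &&
          found$utr_start == off &&
          !.any_site(mirnas[-mi, , drop = FALSE], seq)
        if (!ok) next
        snp <- NULL
        if (runif(1) < snp_in_site_rate) {
          snp <- .plant_site_snp(mirnas, mi, seq, found)
          if (is.null(snp)) next
        }
        utr_rows[[t]] <- .utr_row(tid, gene, seq, chrom, anchor)
        sites[[length(sites) + 1L]] <- data.frame(
          transcript = tid, gene = gene, mirna = mirnas$name[mi],
          site_class = cls, utr_start = found$utr_start,
          utr_end = found$utr_end, stringsAsFactors = FALSE)
        if (!is.null(snp)) {
          gpos <- anchor + snp$offset - 1L
          id <- sprintf("utrsnp%04d", length(snps) + 1L)
          snps[[length(snps) + 1L]] <- data.frame(
            id = id, transcript = tid, mirna = mirnas$name[mi],
            utr_offset = snp$offset, ref = snp$ref, alt = snp$alt,
            chrom = chrom, pos = gpos, stringsAsFactors = FALSE)
          vars[[length(vars) + 1L]] <-
            variant_table(chrom, gpos, id, snp$ref, snp$alt)
        }
        done <- TRUE; break
      }
      if (!done)
        stop("gen_targetome: rejection budget exceeded for transcript ", t,
             "; consider raising utr_len")
    }
    list(utrs = do.call(rbind, c(utr_rows, make.row.names = FALSE)),
         variants = if (length(vars))
           do.call(rbind, c(vars, make.row.names = FALSE))
         else variant_table(character(0), integer(0), character(0),
                            character(0), character(0)),
         truth = list(
           sites = if (length(sites))
             do.call(rbind, c(sites, make.row.names = FALSE)) else NULL,
           snps = if (length(snps))
             do.call(rbind, c(snps, make.row.names = FALSE)) else NULL))
  })
}

.utr_row <- function(tid, gene, seq, chrom, anchor) {
  data.frame(name = tid, kind = "utr", sequence = seq, transcript_id = tid,
             gene_symbol = gene, chrom = chrom, strand = "+",
             utr_genomic_start = anchor, stringsAsFactors = FALSE)
}

.any_site <- function(mirnas, seq) {
  for (i in seq_len(nrow(mirnas)))
    if (nrow(find_seed_sites(mirnas$sequence[i], seq)) > 0L) return(TRUE)
  FALSE
}

# the mRNA-sense site text for a class: revcomp of the seed + t1 A
.site_sequence <- function(mirna_seq, cls) {
  core <- .revcomp_rna_to_dna(substr(mirna_seq, 2, 7))
  m8 <- .dna_comp[[substr(mirna_seq, 8, 8)]]
  switch(cls,
         "8mer"    = paste0(m8, core, "A"),
         "7mer-m8" = paste0(m8, core),
         "7mer-A1" = paste0(core, "A"),
         "6mer"    = core)
}

# choose a seed-pairing position inside the planted site, substitute an alt
# allele that breaks complementarity without creating any new site
.plant_site_snp <- function(mirnas, mi, seq, found) {
  cls <- found$site_class
  # seed-pairing region: the 6mer core plus the m8 base for m8 classes
  core_lo <- found$core_start
  lo <- if (cls %in% c("8mer", "7mer-m8")) core_lo - 1L else core_lo
  hi <- core_lo + 5L
  ref_sites <- find_seed_sites(mirnas$sequence[mi], seq)
  for (try in 1:20) {
    off <- sample(lo:hi, 1L)
    ref <- substr(seq, off, off)
    alt <- sample(setdiff(DNA_BASES, ref), 1L)
    alt_seq <- seq
    substr(alt_seq, off, off) <- alt
    # alt must strictly weaken: no new site for any miRNA, planted site
    # degraded or destroyed
    new_any <- FALSE
    for (k in seq_len(nrow(mirnas))) {
      s_ref <- find_seed_sites(mirnas$sequence[k], seq)
      s_alt <- find_seed_sites(mirnas$sequence[k], alt_seq)
      key <- function(s) paste(s$site_class, s$core_start)
      if (length(setdiff(key(s_alt), key(s_ref))) > 0L) new_any <- TRUE
    }
    if (new_any) next
    return(list(offset = off, ref = ref, alt = alt))
  }
  NULL
}

#' Simulate per-sample expression with a linear per-allele effect
#'
#' `e = intercept + beta * dosage + Normal(0, noise_sd)`; a fraction
#' `outlier_frac` of samples is then shifted by `+/- outlier_shift` (random
#' sign) to exercise the IQR outlier filter.
#'
#' @param dosages numeric vector of allele dosages at one SNP.
#' @param intercept baseline expression (default 400, the scale of
#'   normalized small-RNA quantifications).
#' @param beta_per_allele planted per-allele effect.
#' @param noise_sd residual SD.
#' @param outlier_frac fraction of samples shifted (in `[0, 1)`).
#' @param outlier_shift magnitude of the planted shift (default 1000,
#'   comfortably beyond the 1.5 IQR fences at the default noise).
#' @param seed RNG seed.
#' @return list(expression, truth = list(beta, outlier_idx)).
#' @export
gen_expression <- function(dosages, intercept = 400, beta_per_allele = 80,
                           noise_sd = 120, outlier_frac = 0.05,
                           outlier_shift = 1000, seed = 1L) {
  stopifnot(outlier_frac >= 0, outlier_frac < 1)
  withr::with_seed(seed, {
    n <- length(dosages)
    e <- intercept + beta_per_allele * dosages + rnorm(n, 0, noise_sd)
    n_out <- floor(outlier_frac * n)
    idx <- if (n_out > 0) sample.int(n, n_out) else integer(0)
    if (n_out > 0)
      e[idx] <- e[idx] + sample(c(-1, 1), n_out, replace = TRUE) * outlier_shift
    list(expression = e,
         truth = list(beta = beta_per_allele, outlier_idx = sort(idx)))
  })
}

#' Simulate luciferase reporter plates with a multiplicative allele effect
#'
#' For each experiment, replicate luminescence is generated for the four
#' conditions (ref/alt construct x targeting/scrambled miRNA). Within an
#' experiment, the scrambled-control mean is the experiment baseline
#' (`baseline_mean` with log-normal experiment-level jitter, shared by all
#' four conditions so it cancels in normalized ratios); targeting-miRNA
#' means are `baseline * knockdown_ref` (ref construct) and
#' `baseline * (knockdown_ref + allele_effect)` (alt construct). Replicate
#' noise is multiplicative log-normal with coefficient of variation `cv`.
#' The default cv = 0.08 sits in the typical 5-15% technical-CV range of
#' plate-reader luminescence and satisfies the stated recovery calibration
#' (allele effect within +/- 0.03 in >= 90% of runs at 7 experiments x 6
#' replicates requires a per-ratio SD below ~0.034, i.e. cv below ~0.09).
#'
#' @param n_experiments independent experiments (default 7).
#' @param n_replicates replicates per condition (default 6, >= 2).
#' @param baseline_mean scrambled-control luminescence scale.
#' @param knockdown_ref targeting/scrambled ratio for the ref construct
#'   (default 0.585).
#' @param allele_effect additive difference in that ratio for the alt
#'   construct (default 0.118).
#' @param cv replicate coefficient of variation (log-scale SD).
#' @param baseline_jitter_sd experiment-level log-normal baseline jitter SD.
#' @param seed RNG seed.
#' @return list(data = data.frame(experiment, allele, mirna, replicate,
#'   value), truth = list(knockdown_ref, allele_effect)).
#' @export
gen_plate <- function(n_experiments = 7L, n_replicates = 6L,
                      baseline_mean = 1e5, knockdown_ref = 0.585,
                      allele_effect = 0.118, cv = 0.08,
                      baseline_jitter_sd = 0.2, seed = 1L) {
  stopifnot(n_replicates >= 2L)
  withr::with_seed(seed, {
    rows <- list()
    for (e in seq_len(n_experiments)) {
      base_e <- baseline_mean * exp(rnorm(1, 0, baseline_jitter_sd))
      means <- c(ref.targeting = base_e * knockdown_ref,
                 ref.scrambled = base_e,
                 alt.targeting = base_e * (knockdown_ref + allele_effect),
                 alt.scrambled = base_e)
      for (cond in names(means)) {
        al <- sub("\\..*$", "", cond); mr <- sub("^.*\\.", "", cond)
        vals <- means[[cond]] * exp(rnorm(n_replicates, 0, cv))
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = e, allele = al, mirna = mr,
          replicate = seq_len(n_replicates), value = vals,
          stringsAsFactors = FALSE)
      }
    }
    list(data = do.call(rbind, c(rows, make.row.names = FALSE)),
         truth = list(knockdown_ref = knockdown_ref,
                      allele_effect = allele_effect))
  })
}
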