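# Readers/writers for the standard formats the pipeline touches, plus the
# basic containers: variant tables, genotype matrices, sequence records.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

#' Construct a variant table
#'
#' Biallelic SNPs only: one row per variant with chromosome, 1-based position
#' (VCF convention), id and ref/alt alleles.
#'
#' @param chrom,pos,id,ref,alt vectors of equal length.
#' @return data.frame with columns chrom, pos, id, ref, alt.
#' @export
variant_table <- function(chrom, pos, id, ref, alt) {
  pos <- as.integer(pos)
  stopifnot(all(pos >= 1L), all(ref %in% DNA_BASES), all(alt %in% DNA_BASES))
  if (any(ref == alt)) stop("variant_table: ref and alt alleles must differ")
  data.frame(chrom = as.character(chrom), pos = pos, id = as.character(id),
             ref = as.character(ref), alt = as.character(alt),
             stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' Samples x variants allele-dosage matrix. Dosages are expected alt-allele
#' counts in `[0, 2]` (fractional for imputed data); `NA` marks missing calls.
#' Missing dosages are never imputed here; regression stages mean-impute per
#' variant at fit time.
#'
#' @param sample_ids character vector, unique.
#' @param variants data.frame as from [variant_table()].
#' @param dosages numeric matrix, `length(sample_ids)` rows and
#'   `nrow(variants)` columns.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, variants, dosages) {
  dosages <- as.matrix(dosages)
  stopifnot(is.character(sample_ids), !anyDuplicated(sample_ids),
            nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)
    stop("genotype_matrix: dosages must lie in [0, 2]")
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(list(sample_ids = sample_ids, variants = variants,
                 dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d missing entries)\n",
              length(x$sample_ids), nrow(x$variants), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from a VCF file
#'
#' Biallelic SNP records are kept; multiallelic or non-SNP records are skipped
#' with a logged warning. Per entry, the dosage is taken from the first
#' available field in `dosage_field_preference`: a dosage field (`DS`), a
#' genotype-probability triple (`GP`, as `0*P(0/0) + 1*P(0/1) + 2*P(1/1)`),
#' then the hard genotype (`GT`, alt-allele count; `./.` is missing). Sample
#' order is the VCF header order, never reordered.
#'
#' @param path VCF file (v4.x, plain text or bgzipped).
#' @param dosage_field_preference ordered character vector of FORMAT fields.
#' @return [genotype_matrix()].
#' @export
read_genotypes <- function(path, dosage_field_preference = c("DS", "GP", "GT")) {
  if (!file.exists(path)) stop("read_genotypes: cannot read '", path, "'")
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) == 0L) stop("read_genotypes: VCF contains no samples")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & ref %in% DNA_BASES & alt1 %in% DNA_BASES
  if (any(!keep))
    warning(sum(!keep), " multiallelic/non-SNP record(s) skipped")
  if (!any(keep)) stop("read_genotypes: no biallelic SNP records")
  vars <- variant_table(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos   = GenomicRanges::start(rr)[keep],
    id    = names(rr)[keep],
    ref   = ref[keep], alt = alt1[keep])
  gen <- VariantAnnotation::geno(vcf)
  samples <- colnames(vcf)
  n_var <- sum(keep)
  dos <- matrix(NA_real_, nrow = length(samples), ncol = n_var)
  for (field in dosage_field_preference) {
    if (!field %in% names(gen)) next
    cand <- switch(field,
      DS = t(matrix(as.numeric(gen$DS[keep, , drop = FALSE]), nrow = n_var)),
      GP = {
        gp <- gen$GP
        if (length(dim(gp)) != 3L || dim(gp)[3] < 3L) next
        gp <- gp[keep, , , drop = FALSE]       # variants x samples x 3
        het <- matrix(gp[, , 2], nrow = n_var)
        hom <- matrix(gp[, , 3], nrow = n_var)
        t(het + 2 * hom)
      },
      GT = {
        gt <- gen$GT[keep, , drop = FALSE]
        cnt <- matrix(vapply(gt, .gt_to_dosage, numeric(1)), nrow = n_var)
        t(cnt)
      },
      stop("read_genotypes: unsupported dosage field '", field, "'"))
    fill <- is.na(dos) & !is.na(cand)
    dos[fill] <- cand[fill]
  }
  genotype_matrix(samples, vars, dos)
}

.gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c("./.", ".|.", ".")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  sum(as.numeric(alleles))
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 with `GT` (hard calls when the dosage is integral,
#' `./.` otherwise) and `DS` fields; round-trips through [read_genotypes()].
#'
#' @param gm [genotype_matrix()].
#' @param path output file.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mirsnp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Alt allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")), con)
  dos <- gm$dosages
  for (j in seq_len(nrow(v))) {
    d <- dos[, j]
    gt <- ifelse(is.na(d), "./.",
          ifelse(abs(d - round(d)) < 1e-9,
                 c("0/0", "0/1", "1/1")[round(d) + 1L], "./."))
    ds <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 8))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT:DS",
                       paste(gt, ds, sep = ":")), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read miRNA or 3'UTR sequences from FASTA
#'
#' Sequences are upper-cased; for `kind = "mirna"`, T is transliterated to U
#' and lengths must lie in `[18, 24]`. UTR headers encode metadata as
#' `transcript_id|gene_symbol|chrom|strand|utr_genomic_start` (1-based genomic
#' start, i.e. the smallest genomic coordinate of the UTR); the sequence is
#' always the mRNA-sense strand 5'->3'. Records are kept in file order.
#'
#' @param path FASTA file.
#' @param kind `"mirna"` or `"utr"`.
#' @return data.frame with columns `name`, `kind`, `sequence` and, for UTRs,
#'   `transcript_id`, `gene_symbol`, `chrom`, `strand`, `utr_genomic_start`.
#' @export
read_sequences <- function(path, kind = c("mirna", "utr")) {
  kind <- match.arg(kind)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("read_sequences: empty FASTA '", path, "'")
  seqs <- toupper(as.character(ss))
  if (kind == "mirna") seqs <- chartr("T", "U", seqs)
  alph <- if (kind == "mirna") RNA_BASES else DNA_BASES
  bad <- which(vapply(strsplit(seqs, ""), function(s) any(!s %in% alph), logical(1)))
  if (length(bad))
    stop("read_sequences: record '", names(ss)[bad[1]],
         "' contains characters outside {", paste(alph, collapse = ","), "}")
  names(seqs) <- NULL
  hdr <- names(ss)
  if (kind == "mirna") {
    len <- nchar(seqs)
    if (any(len < 18 | len > 24))
      stop("read_sequences: miRNA '", hdr[which(len < 18 | len > 24)[1]],
           "' length outside [18, 24]")
    return(data.frame(name = hdr, kind = "mirna", sequence = seqs,
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(hdr, "|", fixed = TRUE)
  if (any(lengths(parts) != 5L))
    stop("read_sequences: UTR header must be ",
         "'transcript|gene|chrom|strand|start': '",
         hdr[which(lengths(parts) != 5L)[1]], "'")
  p <- do.call(rbind, parts)
  if (any(!p[, 4] %in% c("+", "-")))
    stop("read_sequences: UTR strand must be '+' or '-'")
  data.frame(name = p[, 1], kind = "utr", sequence = seqs,
             transcript_id = p[, 1], gene_symbol = p[, 2], chrom = p[, 3],
             strand = p[, 4], utr_genomic_start = as.integer(p[, 5]),
             stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' Inverse of [read_sequences()]; UTR metadata is re-encoded into the header.
#'
#' @param records data.frame as returned by [read_sequences()].
#' @param path output FASTA.
#' @export
write_sequences <- function(records, path) {
  hdr <- if (identical(records$kind[1], "utr")) {
    paste(records$transcript_id, records$gene_symbol, records$chrom,
          records$strand, records$utr_genomic_start, sep = "|")
  } else records$name
  ss <- Biostrings::BStringSet(setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Tab-separated with header; first column is the sample id, remaining
#' columns are traits and covariates (the standard covariates are `age` in
#' years, `sex` coded 0/1, `education` in years).
#'
#' @param path TSV file.
#' @return data.frame with column `sample_id` first.
#' @export
read_phenotypes <- function(path) {
  ph <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(ph)[1] <- "sample_id"
  ph$sample_id <- as.character(ph$sample_id)
  if (anyDuplicated(ph$sample_id)) stop("read_phenotypes: duplicate sample ids")
  ph
}

#' @rdname read_phenotypes
#' @param pheno data.frame to write.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an association results table
#'
#' Tab-separated with header columns chrom, pos, id, ref, alt, trait, n,
#' beta, se, t, p; P-values in scientific notation. Read-back reproduces all
#' numeric values to at least 6 significant digits.
#'
#' @param rows data.frame of association rows ([scan_trait()] output).
#' @param path output TSV.
#' @export
write_assoc_table <- function(rows, path) {
  cols <- c("chrom", "pos", "id", "ref", "alt", "trait", "n", "beta", "se", "t", "p")
  if (nrow(rows) == 0L) {
    warning("write_assoc_table: no rows; writing header only")
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- rows[, cols]
  for (nm in c("beta", "se", "t"))
    out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                        formatC(out[[nm]], format = "g", digits = 8))
  out$p <- ifelse(is.na(out$p), "NA", formatC(out$p, format = "e", digits = 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_table
#' @export
read_assoc_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  for (nm in c("n", "beta", "se", "t", "p")) tab[[nm]] <- as.numeric(tab[[nm]])
  tab
}

#' Read gene intervals from BED or TSV
#'
#' BED input (`.bed`) is 0-based half-open and converted to 1-based inclusive;
#' TSV input has header columns `gene_symbol`, `chrom`, `start`, `end`
#' already 1-based inclusive.
#'
#' @param path BED or TSV file.
#' @return data.frame with columns gene_symbol, chrom, start, end.
#' @export
read_gene_intervals <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- data.frame(gene_symbol = as.character(bed[[4]]),
                      chrom = as.character(bed[[1]]),
                      start = as.integer(bed[[2]]) + 1L,
                      end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    out <- data.frame(gene_symbol = as.character(tab$gene_symbol),
                      chrom = as.character(tab$chrom),
                      start = as.integer(tab$start),
                      end = as.integer(tab$end), stringsAsFactors = FALSE)
  }
  if (any(out$start > out$end)) stop("read_gene_intervals: start > end")
  out
}
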