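# Linkage-disequilibrium r^2 and proxy-SNP search around index GWAS SNPs.

#' Pairwise linkage disequilibrium r-squared
#'
#' Haplotype mode computes \eqn{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))} with
#' \eqn{D = p_{AB} - p_A p_B} from phased 0/1 haplotype vectors. Genotype mode
#' is the squared Pearson correlation of dosage vectors (composite LD), an
#' approximation appropriate for unphased cohorts. The result is clamped to
#' `[0, 1]`.
#'
#' @param a,b numeric vectors: alleles in `{0,1}` (haplotype mode) or dosages
#'   in `[0,2]` (genotype mode), equal length.
#' @param mode `"haplotype"` or `"genotype"`.
#' @return scalar r-squared in `[0, 1]`.
#' @export
compute_r2 <- function(a, b, mode = c("haplotype", "genotype")) {
  mode <- match.arg(mode)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (var(a) == 0 || var(b) == 0)
    stop("compute_r2: monomorphic site, r^2 undefined")
  if (mode == "haplotype") {
    if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
      stop("compute_r2: haplotype mode requires 0/1 alleles")
    pA <- mean(a); pB <- mean(b)
    D <- mean(a * b) - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  } else {
    r2 <- cor(a, b)^2
  }
  min(max(r2, 0), 1)
}

#' Find proxy SNPs in LD with index SNPs
#'
#' Every variant on the index SNP's chromosome within `window_bp` and with
#' r-squared at or above `r2_min` is emitted, including the index itself
#' (r2 = 1, distance 0). Results are sorted by descending r2, then distance.
#' An index id absent from the reference data produces a per-index error
#' record (in the `errors` attribute) and the run continues.
#'
#' @param index_ids character vector of index variant ids.
#' @param ref a `haplotype_panel` (phased r2) or [genotype_matrix()]
#'   (composite r2 on dosages).
#' @param r2_min minimum r-squared (default 0.8; the relaxed 0.5 sweep is a
#'   documented alternative).
#' @param window_bp search half-window in bp (default 1e6).
#' @return data.frame with columns index_id, proxy_id, chrom, pos_index,
#'   pos_proxy, ref, alt, r2, distance_bp; attribute `errors` lists index ids
#'   that could not be processed.
#' @export
find_proxies <- function(index_ids, ref, r2_min = 0.8, window_bp = 1e6L) {
  if (inherits(ref, "haplotype_panel")) {
    mat <- ref$haplotypes; vars <- ref$variants; mode <- "haplotype"
  } else if (inherits(ref, "genotype_matrix")) {
    mat <- ref$dosages; vars <- ref$variants; mode <- "genotype"
  } else stop("find_proxies: ref must be a haplotype_panel or genotype_matrix")
  out <- list(); errors <- character(0)
  for (id in index_ids) {
    i <- match(id, vars$id)
    if (is.na(i)) {
      errors <- c(errors, paste0(id, ": not found in reference"))
      next
    }
    cand <- which(vars$chrom == vars$chrom[i] &
                  abs(vars$pos - vars$pos[i]) <= window_bp)
    r2 <- vapply(cand, function(j) {
      if (j == i) return(1)
      tryCatch(compute_r2(mat[, i], mat[, j], mode = mode),
               error = function(e) NA_real_)
    }, numeric(1))
    keep <- !is.na(r2) & r2 >= r2_min
    if (!any(keep)) next
    cand <- cand[keep]; r2 <- r2[keep]
    df <- data.frame(index_id = id, proxy_id = vars$id[cand],
                     chrom = vars$chrom[cand], pos_index = vars$pos[i],
                     pos_proxy = vars$pos[cand],
                     ref = vars$ref[cand], alt = vars$alt[cand],
                     r2 = r2, distance_bp = abs(vars$pos[cand] - vars$pos[i]),
                     stringsAsFactors = FALSE)
    out[[id]] <- df[order(-df$r2, df$distance_bp), ]
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(index_id = character(0), proxy_id = character(0),
               chrom = character(0), pos_index = integer(0),
               pos_proxy = integer(0), ref = character(0), alt = character(0),
               r2 = numeric(0), distance_bp = integer(0))
  attr(res, "errors") <- errors
  res
}
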