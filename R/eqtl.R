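# Expression-QTL stage: IQR outlier filtering, normality check,
# covariate-adjusted additive regression, homozygote-exclusion sensitivity
# analysis.

#' Interquartile-range outlier filter
#'
#' Values more than 1.5 times the IQR below the first quartile or above the
#' third quartile are flagged as outliers; the fences are inclusive (boundary
#' values kept). Quartiles use linear interpolation of order statistics
#' (quantile type 7, the default of the statistical environment the original
#' analysis used); the convention is exposed because borderline exclusion
#' counts can be convention-sensitive.
#'
#' @param values numeric vector (>= 4 non-missing values).
#' @param k fence multiplier (default 1.5).
#' @param type quantile type passed to [stats::quantile()] (default 7).
#' @return list: `keep` (logical mask: TRUE = kept non-missing value, FALSE =
#'   excluded outlier, NA = missing input), `n_excluded`, `fences` (lower,
#'   upper).
#' @export
iqr_filter <- function(values, k = 1.5, type = 7L) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("iqr_filter: need at least 4 non-missing values")
  q <- quantile(values[ok], c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
  keep <- ifelse(ok, values >= lo & values <= hi, NA)
  list(keep = keep, n_excluded = sum(!keep, na.rm = TRUE),
       fences = c(lower = lo, upper = hi))
}

#' Shapiro-Wilk normality check
#'
#' Advisory only: reports the W statistic and P for the filtered expression
#' vector; it never gates the regression.
#'
#' @param values numeric vector, 3 <= n <= 5000 non-missing.
#' @return list(W, p).
#' @export
normality_check <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("normality_check: n must lie in [3, 5000]")
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Covariate-adjusted additive eQTL regression
#'
#' Expression is IQR-filtered (unless `apply_iqr = FALSE`), then regressed by
#' OLS on the minor-allele count plus covariates plus an intercept. Dosages
#' are re-oriented so the reported beta is expression units per minor allele
#' (if the alt allele has frequency > 0.5, dosage is flipped to `2 - d`).
#' Factor covariates (e.g. population of origin) are expanded to indicator
#' columns with the first level dropped. Two-sided P from the t distribution.
#'
#' @param expr numeric expression vector.
#' @param dosages numeric allele-dosage vector, aligned with `expr`.
#' @param covariates optional data.frame of covariates (same order), e.g.
#'   sex and population labels.
#' @param apply_iqr run [iqr_filter()] on `expr` first (default TRUE).
#' @param k,type IQR filter settings.
#' @return list of class `eqtl_result`: n_used, n_excluded_outliers,
#'   n_missing, beta, se, t, p, covariates, flipped (TRUE when dosage was
#'   re-oriented to the minor allele).
#' @export
fit_eqtl <- function(expr, dosages, covariates = NULL, apply_iqr = TRUE,
                     k = 1.5, type = 7L) {
  stopifnot(length(expr) == length(dosages))
  n_in <- length(expr)
  if (apply_iqr) {
    flt <- iqr_filter(expr, k = k, type = type)
    keep <- !is.na(flt$keep) & flt$keep
    n_out <- flt$n_excluded
  } else {
    keep <- !is.na(expr)
    n_out <- 0L
  }
  keep <- keep & !is.na(dosages)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n_in)
    keep <- keep & complete.cases(covariates)
  }
  e <- expr[keep]; d <- dosages[keep]
  flipped <- mean(d) / 2 > 0.5
  if (flipped) d <- 2 - d
  if (var(d) == 0) stop("fit_eqtl: genotype monomorphic after filtering")
  X <- matrix(1, length(e), 1, dimnames = list(NULL, "(Intercept)"))
  cov_names <- character(0)
  if (!is.null(covariates)) {
    cv <- covariates[keep, , drop = FALSE]
    for (nm in names(cv)) {
      col <- cv[[nm]]
      if (is.character(col) || is.factor(col)) {
        col <- factor(col)
        lv <- levels(col)
        if (length(lv) > 1L)
          for (l in lv[-1]) {
            X <- cbind(X, as.numeric(col == l))
            colnames(X)[ncol(X)] <- paste0(nm, l)
          }
      } else {
        X <- cbind(X, as.numeric(col))
        colnames(X)[ncol(X)] <- nm
      }
      cov_names <- c(cov_names, nm)
    }
  }
  X <- cbind(X, dosage = d)
  n <- length(e)
  if (n < ncol(X) + 1L) stop("fit_eqtl: fewer samples than parameters + 1")
  if (var(e) == 0) {
    return(structure(list(n_used = n, n_excluded_outliers = n_out,
                          n_missing = n_in - n - n_out, beta = 0, se = NA_real_,
                          t = 0, p = 1, covariates = cov_names,
                          flipped = flipped), class = "eqtl_result"))
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  b_all <- XtXinv %*% crossprod(X, e)
  resid <- e - X %*% b_all
  rdf <- n - ncol(X)
  sigma2 <- sum(resid^2) / rdf
  se <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
  b <- b_all[ncol(X), 1]
  structure(list(n_used = n, n_excluded_outliers = n_out,
                 n_missing = n_in - n - n_out,
                 beta = b, se = se, t = b / se,
                 p = 2 * pt(-abs(b / se), rdf),
                 covariates = cov_names, flipped = flipped),
            class = "eqtl_result")
}

#' @export
print.eqtl_result <- function(x, ...) {
  cat(sprintf("eQTL fit: n = %d (excluded %d outliers, %d missing)\n",
              x$n_used, x$n_excluded_outliers, x$n_missing))
  cat(sprintf("beta = %.4g per minor allele, SE = %.4g, P = %.4g\n",
              x$beta, x$se, x$p))
  if (length(x$covariates))
    cat("adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Sensitivity analysis excluding one genotype class
#'
#' Outlier filtering is applied on the full expression vector first (as in
#' the primary fit); samples whose rounded minor-allele count equals
#' `excluded_genotype` (default 2, the minor-allele homozygotes) are then
#' dropped and the regression re-fit without re-filtering.
#'
#' @inheritParams fit_eqtl
#' @param excluded_genotype minor-allele count class to drop (0, 1 or 2).
#' @return `eqtl_result` as [fit_eqtl()]; `n_excluded_outliers` counts the
#'   full-vector IQR exclusions.
#' @export
sensitivity_excluding_genotype <- function(expr, dosages, covariates = NULL,
                                           excluded_genotype = 2L,
                                           apply_iqr = TRUE, k = 1.5,
                                           type = 7L) {
  stopifnot(length(expr) == length(dosages))
  if (apply_iqr) {
    flt <- iqr_filter(expr, k = k, type = type)
    keep <- !is.na(flt$keep) & flt$keep
    n_out <- flt$n_excluded
  } else {
    keep <- !is.na(expr); n_out <- 0L
  }
  d_minor <- dosages
  if (mean(dosages, na.rm = TRUE) / 2 > 0.5) d_minor <- 2 - dosages
  keep <- keep & !is.na(d_minor) & round(d_minor) != excluded_genotype
  res <- fit_eqtl(expr[keep], dosages[keep],
                  covariates = if (is.null(covariates)) NULL else
                    covariates[keep, , drop = FALSE],
                  apply_iqr = FALSE)
  res$n_excluded_outliers <- n_out
  res
}

#' Locations of user-supplied GEUVADIS reproduction files
#'
#' The external eQTL reproduction needs two downloads the package cannot
#' fetch: the E-GEUV-2 miRNA quantification release
#' (`GD452.MirnaQuantCount.1.2N.50FN.samplename.resk10.txt`) and a
#' tab-separated genotype table `rs9882688_genotypes.tsv` with columns
#' `sample_id`, `dosage` (minor G-allele count from 1000 Genomes), `sex`,
#' `population` (CEU/FIN/GBR/TSI). Place both under the directory given by
#' `options(mirsnp.geuvadis_dir = ...)` (default `~/mirsnp_geuvadis`).
#'
#' @param dir directory holding the two files.
#' @return list(quant, genotypes) of expected file paths.
#' @export
geuvadis_paths <- function(dir = getOption(
  "mirsnp.geuvadis_dir", file.path(path.expand("~"), "mirsnp_geuvadis"))) {
  list(quant = file.path(dir,
         "GD452.MirnaQuantCount.1.2N.50FN.samplename.resk10.txt"),
       genotypes = file.path(dir, "rs9882688_genotypes.tsv"))
}

#' Read a GEUVADIS-style miRNA quantification matrix
#'
#' Parses the released small-RNA quantification format (miRNAs in rows,
#' samples in columns; the first column holds the miRNA identifier, any
#' additional non-numeric annotation columns are skipped) and returns one
#' miRNA's expression as a named vector.
#'
#' @param path tab-separated quantification file.
#' @param mirna miRNA identifier to extract (matched against the first
#'   column, exact match preferred, substring fallback).
#' @return named numeric vector (names = sample ids).
#' @export
read_mirna_quant <- function(path, mirna) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  key <- as.character(tab[[1]])
  i <- which(key == mirna)
  if (!length(i)) i <- grep(mirna, key, fixed = TRUE)
  if (!length(i)) stop("read_mirna_quant: '", mirna, "' not found")
  if (length(i) > 1L) {
    warning("read_mirna_quant: multiple matches for '", mirna,
            "'; using the first")
    i <- i[1]
  }
  row <- tab[i, -1, drop = FALSE]
  num <- suppressWarnings(vapply(row, function(x) as.numeric(x[1]), numeric(1)))
  num[!is.na(num)]
}
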