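# Additive-model association scan: per-variant OLS with covariate and
# principal-component adjustment, plus greedy locus clumping.

#' Principal components of the genotype matrix
#'
#' Variants are mean-imputed (missing entries), mean-centered and scaled to
#' unit variance; zero-variance variants are dropped with a warning. The
#' top-k right singular directions of the scaled matrix give per-sample
#' scores. Sign convention: in each loading vector the largest-magnitude
#' entry is made positive.
#'
#' @param gm [genotype_matrix()].
#' @param k number of components (>= 1; needs >= k+1 samples).
#' @return numeric matrix, samples x k, columns `PC1..PCk`.
#' @export
compute_pcs <- function(gm, k = 3L) {
  stopifnot(k >= 1L, length(gm$sample_ids) >= k + 1L)
  X <- gm$dosages
  for (j in seq_len(ncol(X))) {
    mj <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mj
  }
  v <- apply(X, 2, var)
  if (all(v == 0)) stop("compute_pcs: all variants have zero variance")
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance variant(s) dropped from PCA")
    X <- X[, v > 0, drop = FALSE]
  }
  Xs <- scale(X)
  pr <- prcomp(Xs, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pr$rotation))
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- gm$sample_ids
  scores
}

#' Per-variant additive linear association scan
#'
#' For each variant, ordinary least squares of the trait on allele dosage
#' plus covariates, principal components and an intercept. Samples with
#' missing trait or covariates are dropped (complete-case); missing dosages
#' are mean-imputed per variant at fit time. Beta/SE/t and the two-sided P
#' come from the t distribution with `n - p` degrees of freedom. Monomorphic
#' variants (and variants monomorphic after complete-case subsetting) emit an
#' NA row with a reason. A constant trait yields beta 0, t 0, p 1 (documented
#' zero-variance policy).
#'
#' Imputed genotypes are handled by regression on expected dosage, the
#' standard asymptotically equivalent replacement for a missing-data
#' likelihood.
#'
#' @param gm [genotype_matrix()].
#' @param pheno data.frame from [read_phenotypes()].
#' @param trait trait column name.
#' @param covariate_names covariate columns of `pheno` to adjust for
#'   (e.g. `c("age", "sex", "education")`).
#' @param pcs optional matrix from [compute_pcs()] (rownames = sample ids).
#' @return data.frame of association rows: chrom, pos, id, ref, alt, trait,
#'   n, beta, se, t, p, reason (NA unless the row is degenerate).
#' @export
scan_trait <- function(gm, pheno, trait, covariate_names = character(0),
                       pcs = NULL) {
  stopifnot(trait %in% names(pheno))
  miss_cov <- setdiff(covariate_names, names(pheno))
  if (length(miss_cov)) stop("scan_trait: covariates not in phenotype table: ",
                             paste(miss_cov, collapse = ", "))
  ph <- pheno[match(gm$sample_ids, pheno$sample_id), , drop = FALSE]
  C <- matrix(1, nrow = length(gm$sample_ids), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  if (length(covariate_names))
    C <- cbind(C, as.matrix(ph[, covariate_names, drop = FALSE]))
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    stopifnot(nrow(pcs) == length(gm$sample_ids))
    C <- cbind(C, pcs)
  }
  y <- ph[[trait]]
  keep <- !is.na(y) & complete.cases(C)
  y <- y[keep]; C <- C[keep, , drop = FALSE]
  n <- length(y); p <- ncol(C) + 1L
  if (n < p + 1L)
    stop("scan_trait: fewer usable samples (", n, ") than parameters + 1")
  y_const <- var(y) == 0
  v <- gm$variants
  out <- v
  out$trait <- trait
  out$n <- n
  out$beta <- out$se <- out$t <- out$p <- NA_real_
  out$reason <- NA_character_
  dos <- gm$dosages[keep, , drop = FALSE]
  for (j in seq_len(ncol(dos))) {
    g <- dos[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (var(g) == 0) { out$reason[j] <- "monomorphic"; next }
    if (y_const) {
      out$beta[j] <- 0; out$t[j] <- 0; out$p[j] <- 1
      out$reason[j] <- "constant_trait"
      next
    }
    X <- cbind(C, dosage = g)
    XtXinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
    if (is.null(XtXinv)) { out$reason[j] <- "collinear"; next }
    b_all <- XtXinv %*% crossprod(X, y)
    resid <- y - X %*% b_all
    rdf <- n - ncol(X)
    sigma2 <- sum(resid^2) / rdf
    se <- sqrt(sigma2 * XtXinv[ncol(X), ncol(X)])
    b <- b_all[ncol(X), 1]
    out$beta[j] <- b
    out$se[j] <- se
    out$t[j] <- b / se
    out$p[j] <- 2 * pt(-abs(b / se), rdf)
  }
  out
}

#' Greedy clumping of association rows into loci
#'
#' Variants with `p <= p_thresh` are merged into a locus when on the same
#' chromosome and within `merge_window_bp` of the growing locus span. The
#' lead variant is the minimum-p variant, ties broken by smaller position.
#' The result is invariant to input row order (rows are sorted internally).
#'
#' @param rows association rows from [scan_trait()].
#' @param p_thresh significance threshold (default suggestive 1e-6; the
#'   genome-wide threshold 5e-8 is the stricter alternative).
#' @param merge_window_bp merge distance (default 1e6).
#' @return data.frame of loci: chrom, start, end, lead_id, lead_pos, min_p,
#'   n_snps.
#' @export
clump_loci <- function(rows, p_thresh = 1e-6, merge_window_bp = 1e6L) {
  sig <- rows[!is.na(rows$p) & rows$p <= p_thresh, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), lead_id = character(0),
                      lead_pos = integer(0), min_p = numeric(0),
                      n_snps = integer(0)))
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  loci <- list(); cur <- NULL
  flush <- function(cur) {
    best <- which(cur$p == min(cur$p))
    best <- best[which.min(cur$pos[best])]
    data.frame(chrom = cur$chrom[1], start = min(cur$pos), end = max(cur$pos),
               lead_id = cur$id[best], lead_pos = cur$pos[best],
               min_p = cur$p[best], n_snps = nrow(cur),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sig))) {
    row <- sig[i, ]
    if (is.null(cur)) { cur <- row; next }
    if (row$chrom == cur$chrom[1] &&
        row$pos - max(cur$pos) <= merge_window_bp) {
      cur <- rbind(cur, row)
    } else {
      loci[[length(loci) + 1L]] <- flush(cur)
      cur <- row
    }
  }
  loci[[length(loci) + 1L]] <- flush(cur)
  do.call(rbind, c(loci, make.row.names = FALSE))
}
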