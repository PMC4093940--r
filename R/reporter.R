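# Luciferase reporter-assay statistics: SD outlier rule, scrambled-control
# normalization, binding and allele tests, percent-point difference.

#' Three-standard-deviation outlier filter for one condition
#'
#' Single pass: mean and SD are computed from all values of the condition,
#' and values deviating more than `k` SDs are removed.
#'
#' @param values replicate luminescence values (>= 3).
#' @param k SD multiplier (default 3; `Inf` is the identity).
#' @return list: `keep` (logical), `values` (kept values), `n_removed`.
#' @export
sd_outlier_filter <- function(values, k = 3) {
  stopifnot(length(values) >= 3L)
  m <- mean(values); s <- sd(values)
  keep <- if (is.infinite(k) || s == 0) rep(TRUE, length(values)) else
    abs(values - m) <= k * s
  list(keep = keep, values = values[keep], n_removed = sum(!keep))
}

.check_reporter <- function(data) {
  stopifnot(all(c("experiment", "allele", "mirna", "value") %in% names(data)))
  stopifnot(all(data$allele %in% c("ref", "alt")),
            all(data$mirna %in% c("targeting", "scrambled")))
  cnt <- table(data$experiment, data$allele, data$mirna)
  if (any(cnt < 2L))
    stop("reporter data: every experiment needs >= 2 replicates in all four conditions")
  invisible(data)
}

#' Apply the SD outlier rule per experimental condition
#'
#' @param data reporter data.frame (experiment, allele, mirna, replicate,
#'   value).
#' @param k SD multiplier (default 3).
#' @return filtered data.frame; attribute `n_removed` logs the removals.
#' @export
filter_reporter_outliers <- function(data, k = 3) {
  .check_reporter(data)
  grp <- interaction(data$experiment, data$allele, data$mirna, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(data)), grp), function(idx) {
    idx[sd_outlier_filter(data$value[idx], k = k)$keep]
  }), use.names = FALSE)
  removed <- nrow(data) - length(keep)
  if (removed > 0) .msg("reporter: removed ", removed, " outlier value(s)")
  out <- data[sort(keep), , drop = FALSE]
  attr(out, "n_removed") <- removed
  out
}

#' Normalize targeting-miRNA luminescence to the scrambled control
#'
#' Within each experiment and allele, the mean luminescence of the
#' targeting-miRNA replicates is divided by the mean of the scrambled
#' (non-targeting) control replicates of the same construct. The ratio is
#' invariant to rescaling all of an experiment's raw values.
#'
#' @param data reporter data.frame.
#' @return data.frame(experiment, allele, ratio).
#' @export
normalize_to_control <- function(data) {
  .check_reporter(data)
  out <- list()
  for (e in unique(data$experiment)) for (al in c("ref", "alt")) {
    t_mean <- mean(data$value[data$experiment == e & data$allele == al &
                                data$mirna == "targeting"])
    c_mean <- mean(data$value[data$experiment == e & data$allele == al &
                                data$mirna == "scrambled"])
    if (!is.finite(c_mean) || c_mean <= 0)
      stop("normalize_to_control: non-positive control mean in experiment ", e)
    out[[length(out) + 1L]] <- data.frame(experiment = e, allele = al,
                                          ratio = t_mean / c_mean,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' One-sample binding test of normalized ratios against 1
#'
#' Tests whether the targeting miRNA suppresses the reporter: one-sample t
#' of the per-experiment ratios against 1 with alternative mean < 1; the
#' reported P is one-tailed (lower tail).
#'
#' @param ratios per-experiment normalized ratios for one allele (>= 2).
#' @return list(t, df, p_one_tailed, mean, se).
#' @export
binding_test <- function(ratios) {
  n <- length(ratios)
  if (n < 2L) stop("binding_test: need >= 2 ratios")
  m <- mean(ratios); se <- sd(ratios) / sqrt(n)
  t <- if (se == 0) {
    if (m == 1) 0 else sign(m - 1) * Inf   # zero-variance ratios
  } else (m - 1) / se
  list(t = t, df = n - 1L, p_one_tailed = pt(t, n - 1L), mean = m, se = se)
}

#' Two-sample allele test on normalized ratios
#'
#' Two-sided t test for independent samples comparing the ref- and
#' alt-construct ratios; Welch degrees of freedom by default, pooled
#' variance by option (which was used originally is not stated).
#'
#' @param ratios_ref,ratios_alt per-experiment ratios (>= 2 each).
#' @param var_equal use the pooled-variance t test (default FALSE = Welch).
#' @return list(t, df, p_two_tailed) with t oriented alt minus ref.
#' @export
allele_test <- function(ratios_ref, ratios_alt, var_equal = FALSE) {
  n1 <- length(ratios_alt); n2 <- length(ratios_ref)
  if (n1 < 2L || n2 < 2L) stop("allele_test: need >= 2 ratios per allele")
  m1 <- mean(ratios_alt); m2 <- mean(ratios_ref)
  v1 <- var(ratios_alt); v2 <- var(ratios_ref)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p_two_tailed = 2 * pt(-abs(t), df))
}

#' Percent-point difference between allele means
#'
#' The allele effect expressed in percentage points of the control-normalized
#' scale: `(mean_alt - mean_ref) * 100`. With normalized means 0.703 (alt)
#' and 0.585 (ref) this reads "the alternative allele increased expression by
#' 11.8%" — the difference of normalized means, not their ratio.
#'
#' @param mean_alt,mean_ref control-normalized allele means, both > 0.
#' @return difference in percentage points.
#' @export
percent_point_difference <- function(mean_alt, mean_ref) {
  stopifnot(mean_alt > 0, mean_ref > 0)
  (mean_alt - mean_ref) * 100
}

#' Full reporter-assay analysis
#'
#' Outlier filtering per condition (filter first, then normalize; the order
#' is configurable via `filter_k = Inf` to disable), control normalization,
#' per-allele binding tests, the two-sample allele test and the percent-point
#' difference.
#'
#' @param data reporter data.frame (experiment, allele, mirna, replicate,
#'   value).
#' @param filter_k SD multiplier for [filter_reporter_outliers()].
#' @param var_equal passed to [allele_test()].
#' @return list of class `reporter_result`: ratios (data.frame), per-allele
#'   mean/se, binding_ref, binding_alt, allele_test,
#'   percent_point_difference, n_outliers_removed.
#' @export
reporter_analysis <- function(data, filter_k = 3, var_equal = FALSE) {
  flt <- filter_reporter_outliers(data, k = filter_k)
  ratios <- normalize_to_control(flt)
  r_ref <- ratios$ratio[ratios$allele == "ref"]
  r_alt <- ratios$ratio[ratios$allele == "alt"]
  structure(list(
    ratios = ratios,
    mean_ref = mean(r_ref), se_ref = sd(r_ref) / sqrt(length(r_ref)),
    mean_alt = mean(r_alt), se_alt = sd(r_alt) / sqrt(length(r_alt)),
    binding_ref = binding_test(r_ref),
    binding_alt = binding_test(r_alt),
    allele_test = allele_test(r_ref, r_alt, var_equal = var_equal),
    percent_point_difference =
      percent_point_difference(mean(r_alt), mean(r_ref)),
    n_outliers_removed = attr(flt, "n_removed")),
    class = "reporter_result")
}

#' @export
print.reporter_result <- function(x, ...) {
  cat(sprintf("reporter: ref ratio %.3f (SE %.4f), alt ratio %.3f (SE %.4f)\n",
              x$mean_ref, x$se_ref, x$mean_alt, x$se_alt))
  cat(sprintf("binding (one-tailed): ref P = %.3g, alt P = %.3g\n",
              x$binding_ref$p_one_tailed, x$binding_alt$p_one_tailed))
  cat(sprintf("allele test (two-tailed): t = %.3f, P = %.4g\n",
              x$allele_test$t, x$allele_test$p_two_tailed))
  cat(sprintf("alt vs ref: %+.1f percentage points\n",
              x$percent_point_difference))
  invisible(x)
}
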