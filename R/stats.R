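# Comparison layer: pooled-variance Student's t and two-sample
# Kolmogorov-Smirnov tests (closed forms, cross-checked in the test suite
# against stats::t.test / stats::ks.test), differential family calls,
# expression filtering, and stoichiometry summaries.

#' Two-sample Student's t-test (pooled variance)
#'
#' @param x,y numeric samples (each n >= 2).
#' @return list of class `srna_test` with `statistic`, `p_value`,
#'   `test = "two_sample_t"`, `df`, `n1`, `n2`.
#' @export
two_sample_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop_fmt("both samples need n >= 2")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * stats::var(x) + (n2 - 1L) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    t <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    t <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  structure(list(statistic = t, p_value = p, test = "two_sample_t",
                 df = df, n1 = n1, n2 = n2), class = "srna_test")
}

# D statistic only (used both by ks_two_sample and by the design module's
# MFE distribution matching)
ks_statistic <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop_fmt("empty sample")
  pts <- sort(unique(c(x, y)))
  ex <- vapply(pts, function(p) mean(x <= p), 0)
  ey <- vapply(pts, function(p) mean(y <= p), 0)
  max(abs(ex - ey))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical CDFs;
#' the two-sided p-value uses the asymptotic Kolmogorov distribution
#' (exact small-sample p-values are not attempted).
#'
#' @param x,y numeric samples (each n >= 1).
#' @return list of class `srna_test` with `statistic` (D), `p_value`,
#'   `test = "ks_two_sample"`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  d <- ks_statistic(x, y)
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * d
  p <- if (lambda < 1e-12) {
    1
  } else if (lambda < 1) {
    # theta-function form, numerically stable for small lambda
    k <- seq_len(6L)
    1 - sqrt(2 * pi) / lambda *
      sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
  } else {
    k <- seq_len(101L)
    2 * sum((-1)^(k - 1L) * exp(-2 * k^2 * lambda^2))
  }
  p <- min(1, max(0, p))
  structure(list(statistic = d, p_value = p, test = "ks_two_sample",
                 n1 = n1, n2 = n2), class = "srna_test")
}

#' @export
print.srna_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$test, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Call differentially abundant families between two groups
#'
#' A family is called `up` (higher in group B) or `down` when the ratio of
#' replicate means reaches `fold` (or its reciprocal) AND the two-sample
#' Student's t-test p-value is below `alpha`; otherwise `ns`. The same
#' rule applies whether the inputs are RPM or MPU tables. No
#' multiple-testing correction is applied by default; `adjust = "BH"`
#' applies Benjamini-Hochberg to the p-values before thresholding.
#'
#' @param group_a,group_b numeric matrices (families x replicates) with
#'   family ids as row names; >= 2 replicates each.
#' @param fold fold-change threshold (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data frame `family_id`, `mean_a`, `mean_b`, `ratio`
#'   (mean_b/mean_a), `p_value`, `call` in \{up, down, ns\}.
#' @export
call_differential <- function(group_a, group_b, fold = 2, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (ncol(group_a) < 2L || ncol(group_b) < 2L)
    stop_fmt("need >= 2 replicates per group")
  fams <- union(rownames(group_a), rownames(group_b))
  shared <- intersect(rownames(group_a), rownames(group_b))
  if (length(shared) < length(fams))
    warn_fmt("%d families missing from one group; called ns",
             length(fams) - length(shared))
  res <- data.frame(family_id = fams,
                    mean_a = NA_real_, mean_b = NA_real_,
                    ratio = NA_real_, p_value = NA_real_,
                    call = "ns", stringsAsFactors = FALSE)
  for (i in seq_along(fams)) {
    f <- fams[i]
    if (!f %in% shared) next
    a <- group_a[f, ]; b <- group_b[f, ]
    res$mean_a[i] <- mean(a); res$mean_b[i] <- mean(b)
    res$ratio[i] <- if (mean(a) > 0) mean(b) / mean(a) else Inf
    res$p_value[i] <- two_sample_t(a, b)$p_value
  }
  p_eff <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  sig <- !is.na(p_eff) & p_eff < alpha
  res$call[sig & res$ratio >= fold] <- "up"
  res$call[sig & res$ratio <= 1 / fold] <- "down"
  res
}

#' Filter families expressed in every replicate
#'
#' Retains families with relative abundance at or above `min_rpm`
#' (inclusive) in every replicate of every supplied sample.
#'
#' @param ... one or more numeric matrices (families x replicates) with
#'   family ids as row names.
#' @param min_rpm threshold (default 1 RPM).
#' @return character vector of retained family ids.
#' @export
filter_expressed <- function(..., min_rpm = 1) {
  mats <- list(...)
  fams <- Reduce(intersect, lapply(mats, rownames))
  keep <- vapply(fams, function(f)
    all(vapply(mats, function(m) all(m[f, ] >= min_rpm), TRUE)), TRUE)
  fams[keep]
}

#' sRNA:precursor / sRNA:target stoichiometry
#'
#' Computes the ratio of mature sRNA MPU to partner (precursor or target
#' mRNA) MPU for each supplied pair, and the group median. Pairs whose
#' partner MPU is undefined (e.g. TPM below the conversion threshold
#' upstream) or zero are dropped and counted.
#'
#' @param mature_mpu data frame `feature_id`, `mpu` (or `absolute_mpu`)
#'   for mature sRNA families.
#' @param partner_mpu same for partner transcripts.
#' @param pairs data frame `mature_id`, `partner_id`.
#' @return list with `ratios` (data frame `mature_id`, `partner_id`,
#'   `mature_mpu`, `partner_mpu`, `ratio`), `median_ratio` and
#'   `n_dropped`.
#' @export
stoichiometry <- function(mature_mpu, partner_mpu, pairs) {
  mpu_col <- function(x) if ("mpu" %in% names(x)) x$mpu else x$absolute_mpu
  id_col <- function(x) if ("feature_id" %in% names(x)) x$feature_id else x$family_id
  m <- mpu_col(mature_mpu)[match(pairs$mature_id, id_col(mature_mpu))]
  p <- mpu_col(partner_mpu)[match(pairs$partner_id, id_col(partner_mpu))]
  ok <- !is.na(m) & !is.na(p) & p > 0
  ratios <- data.frame(mature_id = pairs$mature_id[ok],
                       partner_id = pairs$partner_id[ok],
                       mature_mpu = m[ok], partner_mpu = p[ok],
                       ratio = m[ok] / p[ok], stringsAsFactors = FALSE)
  list(ratios = ratios,
       median_ratio = if (nrow(ratios)) stats::median(ratios$ratio) else NA_real_,
       n_dropped = sum(!ok))
}
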