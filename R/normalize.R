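# Spike-in standard curves: relative units (RPM for sRNA, TPM for mRNA)
# versus known molecules per microgram total RNA (MPU). The default fit is
# least squares of log10(MPU) on log10(relative); a linear-scale fit is
# available. `standard_curve` objects carry the Pearson correlation of the
# calibration points and its two-sided p-value.

#' Reads per million genome-matching reads
#'
#' @param count weighted read count.
#' @param genome_matching_total weighted count of genome-matching reads
#'   (spike-in reads are excluded from this denominator).
#' @return RPM value.
#' @export
compute_rpm <- function(count, genome_matching_total) {
  if (!is.finite(genome_matching_total) || genome_matching_total <= 0)
    stop_fmt("genome_matching_total must be > 0")
  count / genome_matching_total * 1e6
}

#' Fit a spike-in standard curve
#'
#' Fits relative abundance (RPM or TPM) against known absolute input
#' amount (molecules per microgram total RNA). On the default log10 scale,
#' calibration points with non-positive relative values are dropped with a
#' warning (a spike-in set that received no reads cannot constrain the
#' fit).
#'
#' @param relative numeric vector of relative abundances.
#' @param known_mpu numeric vector of known absolute amounts.
#' @param scale `"log10"` (fit log10(MPU) ~ log10(relative); default) or
#'   `"linear"`.
#' @param platform free-text label (`"srna_rpm"` or `"mrna_tpm"`).
#' @return object of class `standard_curve` with components `slope`,
#'   `intercept`, `scale`, `pearson_r`, `p_value`, `n_points`, `platform`,
#'   `data` and the underlying `lm` fit.
#' @seealso [to_mpu()], [predict.standard_curve()]
#' @export
standard_curve <- function(relative, known_mpu,
                           scale = c("log10", "linear"),
                           platform = "srna_rpm") {
  scale <- match.arg(scale)
  if (length(relative) != length(known_mpu))
    stop_fmt("relative and known_mpu must have the same length")
  keep <- is.finite(relative) & is.finite(known_mpu)
  if (scale == "log10") {
    pos <- keep & relative > 0 & known_mpu > 0
    if (any(keep & !pos))
      warn_fmt("%d calibration point(s) with non-positive values dropped from log-scale fit",
               sum(keep & !pos))
    keep <- pos
  }
  x <- relative[keep]
  y <- known_mpu[keep]
  if (length(x) < 2L)
    stop_fmt("need >= 2 usable calibration points, got %d", length(x))
  if (scale == "log10") { xf <- log10(x); yf <- log10(y) } else { xf <- x; yf <- y }
  fit <- stats::lm(yf ~ xf)
  r <- stats::cor(xf, yf)
  p <- if (length(x) > 2L && abs(r) < 1) {
    stats::cor.test(xf, yf, method = "pearson")$p.value
  } else if (abs(r) >= 1 - 1e-15) 0 else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 scale = scale, pearson_r = r, p_value = p,
                 n_points = length(x), platform = platform,
                 data = data.frame(relative = x, known_mpu = y),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Spike-in standard curve (%s, %s scale)\n", x$platform, x$scale))
  if (x$scale == "log10")
    cat(sprintf("  log10(MPU) = %.4f * log10(relative) + %.4f\n",
                x$slope, x$intercept))
  else
    cat(sprintf("  MPU = %.4g * relative + %.4g\n", x$slope, x$intercept))
  cat(sprintf("  n = %d points, Pearson r = %.4f, p = %.3g\n",
              x$n_points, x$pearson_r, x$p_value))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.standard_curve <- function(object, ...) {
  out <- list(curve = object, lm_summary = summary(object$fit))
  class(out) <- "summary.standard_curve"
  out
}

#' @export
print.summary.standard_curve <- function(x, ...) {
  print(x$curve)
  cat("\nUnderlying least-squares fit:\n")
  print(x$lm_summary)
  invisible(x)
}

#' @export
residuals.standard_curve <- function(object, ...) stats::residuals(object$fit)

#' Predict absolute amounts from a standard curve
#'
#' @param object a `standard_curve`.
#' @param relative numeric vector of relative abundances (>= 0); on the
#'   log10 scale, 0 maps to 0 MPU by convention.
#' @param ... unused.
#' @return numeric vector of molecules per microgram total RNA.
#' @export
predict.standard_curve <- function(object, relative, ...) {
  if (any(relative < 0, na.rm = TRUE))
    stop_fmt("relative abundances must be >= 0")
  out <- rep(NA_real_, length(relative))
  ok <- !is.na(relative)
  if (object$scale == "log10") {
    pos <- ok & relative > 0
    out[pos] <- 10^(object$slope * log10(relative[pos]) + object$intercept)
    out[ok & relative == 0] <- 0
  } else {
    out[ok] <- object$slope * relative[ok] + object$intercept
  }
  out
}

#' Convert a relative abundance to molecules per microgram
#'
#' Thin alias of [predict.standard_curve()] under the name used
#' throughout the quantification tables.
#'
#' @param curve a [standard_curve()].
#' @param relative numeric vector (>= 0).
#' @return numeric vector of MPU values.
#' @export
to_mpu <- function(curve, relative) predict(curve, relative)

#' @export
plot.standard_curve <- function(x, ...) {
  log_axes <- if (x$scale == "log10") "xy" else ""
  graphics::plot(x$data$relative, x$data$known_mpu, log = log_axes,
                 xlab = if (x$platform == "mrna_tpm") "TPM" else "RPM",
                 ylab = "molecules per µg total RNA",
                 main = sprintf("Standard curve (r = %.3f)", x$pearson_r), ...)
  rng <- range(x$data$relative)
  xx <- if (x$scale == "log10")
    10^seq(log10(rng[1L]), log10(rng[2L]), length.out = 50L)
  else seq(rng[1L], rng[2L], length.out = 50L)
  graphics::lines(xx, predict(x, xx), lty = 2L)
  invisible(x)
}

#' Fit the sRNA spike-in curve and convert family RPMs to MPU
#'
#' @param families family table with an `rpm` column (from
#'   [quantify_families()]).
#' @param spikein_counts per-set counts from [count_spikein_tags()] (or
#'   the `spikein` element of [align_perfect()]).
#' @param genome_matching_total RPM denominator for the spike-in counts.
#' @param scale fit scale, see [standard_curve()].
#' @return list with `families` (input plus `mpu` column) and `curve`.
#' @export
normalize_families <- function(families, spikein_counts,
                               genome_matching_total,
                               scale = c("log10", "linear")) {
  rpm_spike <- vapply(spikein_counts$count, compute_rpm, 0,
                      genome_matching_total = genome_matching_total)
  curve <- standard_curve(rpm_spike, spikein_counts$molecules_per_ug,
                          scale = match.arg(scale), platform = "srna_rpm")
  families$mpu <- to_mpu(curve, families$rpm)
  list(families = families, curve = curve)
}

#' Convert mRNA TPMs to MPU via ERCC spike-ins
#'
#' Fits the ERCC standard curve (TPM versus known molecules per microgram)
#' and applies it to transcripts with TPM at or above `min_tpm`;
#' lower-expressed transcripts get an undefined (NA) MPU.
#'
#' @param tpm_table data frame `transcript_id`, `tpm` (must contain the
#'   ERCC rows).
#' @param ercc_sheet data frame `ercc_id`, `molecules_per_ug`.
#' @param min_tpm minimum TPM for conversion (default 1.0).
#' @param scale fit scale.
#' @return list with `records` (data frame `feature_id`, `relative`,
#'   `absolute_mpu`) and `curve` (ERCC `standard_curve`).
#' @export
mrna_to_mpu <- function(tpm_table, ercc_sheet, min_tpm = 1.0,
                        scale = c("log10", "linear")) {
  idx <- match(ercc_sheet$ercc_id, tpm_table$transcript_id)
  found <- !is.na(idx)
  if (sum(found) < 2L)
    stop_fmt("fewer than 2 ERCC spike-ins detected in the TPM table")
  curve <- standard_curve(tpm_table$tpm[idx[found]],
                          ercc_sheet$molecules_per_ug[found],
                          scale = match.arg(scale), platform = "mrna_tpm")
  is_ercc <- tpm_table$transcript_id %in% ercc_sheet$ercc_id
  rec <- data.frame(feature_id = tpm_table$transcript_id[!is_ercc],
                    relative = tpm_table$tpm[!is_ercc],
                    stringsAsFactors = FALSE)
  rec$absolute_mpu <- ifelse(rec$relative >= min_tpm,
                             to_mpu(curve, rec$relative), NA_real_)
  list(records = rec, curve = curve)
}
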