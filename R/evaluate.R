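# -- Evaluation statistics ----------------------------------------------------

#' Mean intensity within an organ
#'
#' @param volume A [pet_volume()] (or any list with a `voxels` array, e.g.
#'   the output of [zscore_normalize()]).
#' @param organ_mask Non-empty [pet_mask()] aligned to the volume.
#' @return The arithmetic mean of the voxels under the mask.
#' @export
organ_mean <- function(volume, organ_mask) {
  stopifnot(inherits(organ_mask, "pet_mask"))
  if (!identical(dim(volume$voxels), dim(organ_mask$voxels)))
    stop("mask grid shape does not match the volume")
  if (!any(organ_mask$voxels))
    stop("empty organ mask")
  mean(volume$voxels[organ_mask$voxels])
}

#' Coefficient of variation of organ means across a cohort
#'
#' SD of the per-image organ means divided by their mean. Scale-invariant:
#' a common multiplicative factor on all means cancels.
#'
#' @param means Numeric vector of per-image organ means (length >= 2).
#' @param sd_convention `"population"` or `"sample"`.
#' @return The coefficient of variation as a fraction (multiply by 100 for
#'   the conventional percentage).
#' @export
cv_metric <- function(means, sd_convention = "population") {
  if (length(means) < 2L)
    stop("cv_metric needs at least 2 means")
  m <- mean(means)
  if (m == 0)
    stop("mean of means is zero; CV undefined")
  sd_conv(means, sd_convention) / m
}

#' Mean absolute normalized difference over repeat-scan pairs
#'
#' For each pair of repeat scans of one subject the absolute difference of
#' organ means, normalized by the pair average, is taken; the metric is the
#' mean over pairs. Symmetric within each pair and scale-invariant.
#'
#' @param pairs A two-column numeric matrix (or data.frame) of per-pair organ
#'   means, or a list of length-2 numeric vectors.
#' @return The mean normalized difference as a fraction.
#' @export
md_metric <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || nrow(pairs) < 1L)
    stop("pairs must be n x 2")
  s <- pairs[, 1] + pairs[, 2]
  if (any(s <= 0))
    stop("each pair must have a positive sum of means")
  mean(abs(pairs[, 1] - pairs[, 2]) / (s / 2))
}

#' Two-group comparison of organ means (inter-scanner experiment)
#'
#' Welch's two-sample t-test (Student's via `var_equal = TRUE`) on the organ
#' means of two cohorts, e.g. scans from two scanner models. After effective
#' standardization the group means are expected to be statistically
#' indistinguishable. Degenerate input (both groups constant) is handled
#' explicitly: equal constants give t = 0, p = 1; different constants give
#' p = 0.
#'
#' @param means_group1,means_group2 Numeric vectors of organ means (>= 2
#'   each).
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @param sd_convention Convention for the reported group SDs (the t-test
#'   itself uses its own standard internals).
#' @return A list with `M1`, `S1`, `M2`, `S2`, `t`, `p`, `df`.
#' @export
interscanner_compare <- function(means_group1, means_group2,
                                 var_equal = FALSE,
                                 sd_convention = "population") {
  if (length(means_group1) < 2L || length(means_group2) < 2L)
    stop("each group needs at least 2 means")
  M1 <- mean(means_group1); M2 <- mean(means_group2)
  S1 <- sd_conv(means_group1, sd_convention)
  S2 <- sd_conv(means_group2, sd_convention)
  if (stats::sd(means_group1) == 0 && stats::sd(means_group2) == 0) {
    if (M1 == M2) {
      return(list(M1 = M1, S1 = S1, M2 = M2, S2 = S2,
                  t = 0, p = 1, df = NA_real_))
    }
    return(list(M1 = M1, S1 = S1, M2 = M2, S2 = S2,
                t = Inf, p = 0, df = NA_real_))
  }
  tt <- stats::t.test(means_group1, means_group2, var.equal = var_equal)
  list(M1 = M1, S1 = S1, M2 = M2, S2 = S2,
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Assemble a tidy evaluation report
#'
#' Rows of (metric, organ, method, value in %) mirroring the tabular layout
#' used to compare normalizers; values supplied as fractions are converted
#' to percentages.
#'
#' @param metric Metric name(s), e.g. `"CV"` or `"MD"`.
#' @param organ Organ name(s).
#' @param method Method label(s), e.g. `"raw"`, `"s-AC"`, `"gaussian"`.
#' @param value Metric value(s) as fractions.
#' @return A data.frame with columns `metric`, `organ`, `method`,
#'   `value_pct`.
#' @export
cohort_report <- function(metric, organ, method, value) {
  data.frame(metric = metric, organ = organ, method = method,
             value_pct = 100 * value, stringsAsFactors = FALSE)
}

#' Write an evaluation report as CSV
#'
#' @param report A data.frame from [cohort_report()] (rows may be
#'   concatenated with `rbind`).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
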