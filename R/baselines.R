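# -- Comparison normalizers ---------------------------------------------------
#
# Three baselines: Gaussian (divide by the within-organ SD), Z-score
# (subtract the calibration-cohort organ mean, then divide by the
# within-organ SD), and a simplified histogram-landmark method with a fixed
# upper cutoff. The first two need an organ segmentation of every test image
# and are strictly meaningful only inside the organ; here the whole image is
# normalized and evaluation reads means within organs only.

#' Gaussian normalization
#'
#' Divides every voxel by the standard deviation of intensities inside the
#' reference organ of the same image. Invariant to multiplicative gain on the
#' input (the SD scales with the gain).
#'
#' @param volume A [pet_volume()].
#' @param organ_mask Non-empty organ [pet_mask()] with non-constant
#'   intensities.
#' @param sd_convention `"population"` or `"sample"`.
#' @return A normalized [pet_volume()] (modality preserved; unit scale lost).
#' @export
gaussian_normalize <- function(volume, organ_mask,
                               sd_convention = "population") {
  check_aligned(volume, organ_mask)
  sigma <- sd_conv(volume$voxels[organ_mask$voxels], sd_convention)
  if (sigma <= 0)
    stop("organ intensities are constant (zero SD); Gaussian normalization undefined")
  pet_volume(volume$voxels / sigma, spacing = volume$spacing,
             modality = volume$modality, units = "")
}

#' Z-score normalization
#'
#' Subtracts the calibration-cohort organ mean `mu_ref`, then divides by the
#' within-organ SD of this image. Negative values are legitimate here (the
#' output is a Z-score, not an activity), so the result is returned as a
#' plain array-backed object rather than a [pet_volume()].
#'
#' @inheritParams gaussian_normalize
#' @param mu_ref Calibration-cohort mean of the organ means, see
#'   [cohort_organ_mean()].
#' @return A list with `voxels` (3D array, possibly negative), `spacing` and
#'   `modality`, mirroring the [pet_volume()] layout.
#' @export
zscore_normalize <- function(volume, organ_mask, mu_ref,
                             sd_convention = "population") {
  check_aligned(volume, organ_mask)
  sigma <- sd_conv(volume$voxels[organ_mask$voxels], sd_convention)
  if (sigma <= 0)
    stop("organ intensities are constant (zero SD); Z-score normalization undefined")
  list(voxels = (volume$voxels - mu_ref) / sigma,
       spacing = volume$spacing, modality = volume$modality)
}

#' Calibration-cohort organ mean
#'
#' Mean over the cohort of the within-organ mean intensities; the reference
#' value subtracted by [zscore_normalize()].
#'
#' @param cohort List of [pet_volume()]s.
#' @param organ_masks Organ masks aligned 1:1 with the cohort.
#' @return A single mean intensity.
#' @export
cohort_organ_mean <- function(cohort, organ_masks) {
  if (length(cohort) != length(organ_masks))
    stop("cohort and organ_masks must be aligned 1:1")
  mean(mapply(function(v, m) organ_mean(v, m), cohort, organ_masks))
}

#' Simplified histogram-landmark calibration
#'
#' A reduced landmark-matching normalizer used as a structural comparator:
#' per-image landmarks at fixed percentiles (minimum, median and a fixed
#' 99.8th percentile of the body region — no reference-organ-driven
#' optimization of the upper cutoff), mapped piecewise-linearly onto a fixed
#' standard scale whose median position is the cohort mean of the mapped
#' medians. No inverse scaling is applied. Because the fixed cutoff sits
#' inside the highly variable high-uptake tail whenever lesions occupy more
#' than 0.2% of the body, this method inherits that variability — which is
#' precisely what the optimized upper percentile avoids.
#'
#' @param cohort List of [pet_volume()]s (normal scans).
#' @param s_max Fixed standard-scale ceiling.
#' @param cutoff Fixed upper percentile (default 99.8).
#' @return An object of class `nyul_scale` with `s_med`, `s_max`, `cutoff`,
#'   `calibration_n`.
#' @export
nyul_calibrate <- function(cohort, s_max = 5.00, cutoff = 99.8) {
  if (length(cohort) < 2L)
    stop("landmark calibration needs at least 2 images")
  med <- vapply(cohort, function(vol) {
    body <- body_mask(vol)
    bv <- vol$voxels[body$voxels]
    p0 <- min(vol$voxels)
    p50 <- pet_percentile(bv, 50)
    pc <- pet_percentile(bv, cutoff)
    if (!(p0 < p50 && p50 < pc))
      stop("degenerate landmarks in landmark calibration")
    s_max * (p50 - p0) / (pc - p0)
  }, numeric(1))
  structure(list(s_med = mean(med), s_max = s_max, cutoff = cutoff,
                 calibration_n = length(cohort)),
            class = "nyul_scale")
}

#' Simplified histogram-landmark standardization
#'
#' Maps an image onto the fixed scale of [nyul_calibrate()]: the image's
#' minimum, body median and fixed-cutoff percentile are matched to
#' (0, s_med, s_max) by two linear segments, extrapolated at both tails.
#'
#' @param volume A [pet_volume()].
#' @param nscale A `nyul_scale` from [nyul_calibrate()].
#' @return A [pet_volume()] of modality `STD_AC`/`STD_SUV`.
#' @export
nyul_standardize <- function(volume, nscale) {
  stopifnot(inherits(volume, "pet_volume"), inherits(nscale, "nyul_scale"))
  body <- body_mask(volume)
  bv <- volume$voxels[body$voxels]
  p0 <- min(volume$voxels)
  p50 <- pet_percentile(bv, 50)
  pc <- pet_percentile(bv, nscale$cutoff)
  if (!(p0 < p50 && p50 < pc))
    stop("degenerate landmarks; cannot standardize")
  slope1 <- nscale$s_med / (p50 - p0)
  slope2 <- (nscale$s_max - nscale$s_med) / (pc - p50)
  x <- as.vector(volume$voxels)
  lower <- x <= p50
  out <- numeric(length(x))
  out[lower] <- slope1 * (x[lower] - p0)
  out[!lower] <- nscale$s_med + slope2 * (x[!lower] - p50)
  pet_volume(array(out, dim = dim(volume$voxels)), spacing = volume$spacing,
             modality = paste0("STD_", base_modality(volume$modality)),
             units = "")
}
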