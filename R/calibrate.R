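# -- Calibration: one-time estimation of the standard scale ------------------
#
# The calibration cohort consists of normal scans with a reference-organ mask
# (liver or spleen). Only the two-landmark linear map
#   lambda: [p_alpha(I), p_b(I)] -> [0, s_max]
# is used during calibration; the three-landmark piecewise map cannot exist
# yet because its middle landmark s_m is itself a calibration product.

# per-image quantities the calibration loop needs, computed once:
# the whole-volume minimum (p_alpha), the body-median, the organ mean, and
# the body-region voxel vector for percentile queries.
cohort_landmark_cache <- function(cohort, organ_masks = NULL) {
  n <- length(cohort)
  if (!is.null(organ_masks) && length(organ_masks) != n)
    stop("cohort and organ_masks must be aligned 1:1")
  lapply(seq_len(n), function(i) {
    vol <- cohort[[i]]
    stopifnot(inherits(vol, "pet_volume"))
    body <- body_mask(vol)
    bv <- vol$voxels[body$voxels]
    organ_mu <- NULL
    if (!is.null(organ_masks)) {
      check_aligned(vol, organ_masks[[i]])
      organ_mu <- mean(vol$voxels[organ_masks[[i]]$voxels])
    }
    list(p_alpha = min(vol$voxels), body_values = bv,
         p_m = pet_percentile(bv, 50), organ_mu = organ_mu)
  })
}

# lambda-mapped organ mean for one cached image at upper percentile b:
# lambda(x) = s_max * (x - p_alpha) / (p_b - p_alpha), and by linearity the
# organ mean of lambda(I) equals lambda(organ mean of I).
lambda_organ_mean <- function(cache_i, b, s_max) {
  p_b <- pet_percentile(cache_i$body_values, b)
  den <- p_b - cache_i$p_alpha
  if (den <= 0)
    stop("degenerate landmark set: p_b must exceed p_alpha (b = ", b, ")")
  s_max * (cache_i$organ_mu - cache_i$p_alpha) / den
}

#' Cohort coefficient of variation of the scaled reference-organ mean
#'
#' For a candidate upper percentile `b`, each cohort image is mapped linearly
#' from \[p_alpha(I), p_b(I)\] onto \[0, s_max\] and the mean intensity within
#' the reference organ of the mapped image is taken; `delta_cv` returns the
#' coefficient of variation (SD / mean) of those organ means across the
#' cohort. This is the objective the upper-percentile search minimizes: a
#' small value means `p_b` is an equally reliable anchor in every subject.
#'
#' @param cohort List of [pet_volume()]s (normal scans, one modality).
#' @param organ_masks List of reference-organ [pet_mask()]s aligned 1:1 with
#'   the cohort, each non-empty.
#' @param b Upper percentile in (0, 100\].
#' @param s_max Standard-scale ceiling (cancels in the CV; kept for the
#'   mapped means to be on the standard scale).
#' @param sd_convention `"population"` or `"sample"`.
#' @return The coefficient of variation (a fraction, not a percentage).
#' @export
delta_cv <- function(cohort, organ_masks, b, s_max,
                     sd_convention = "population") {
  if (length(cohort) < 2L)
    stop("delta_cv needs a cohort of at least 2 images")
  cache <- cohort_landmark_cache(cohort, organ_masks)
  mus <- vapply(cache, lambda_organ_mean, numeric(1), b = b, s_max = s_max)
  sd_conv(mus, sd_convention) / mean(mus)
}

#' Grid search for the optimal upper percentile
#'
#' Evaluates the cohort coefficient of variation [delta_cv()] on the grid
#' `b_low, b_low + step, ..., b_high` and returns the largest grid percentile
#' attaining the minimum (ties, e.g. on gain-only cohorts where every grid
#' point gives CV ~ 0, are broken toward the largest b). The optimum `beta`
#' separates stable normal-uptake intensities from the highly variable
#' high-uptake tail: the CV rises sharply once `b` crosses into intensities
#' dominated by lesions and outliers.
#'
#' @inheritParams delta_cv
#' @param b_low,b_high Search interval bounds (defaults \[90, 100\]).
#' @param step Grid step (default 0.1).
#' @return An object of class `beta_search`: a list with `grid` (data.frame
#'   of `b` and `delta`), `beta`, and `delta_at_beta`.
#' @export
optimize_beta <- function(cohort, organ_masks, b_low = 90, b_high = 100,
                          step = 0.1, s_max = 5,
                          sd_convention = "population") {
  if (length(cohort) < 2L)
    stop("optimize_beta needs a cohort of at least 2 images")
  if (b_low > b_high) stop("b_low must be <= b_high")
  if (step <= 0) stop("step must be positive")
  grid_b <- seq(b_low, b_high, by = step)
  if (grid_b[length(grid_b)] < b_high - 1e-9)
    grid_b <- c(grid_b, b_high)
  cache <- cohort_landmark_cache(cohort, organ_masks)

  # one quantile() call per image covers the whole grid
  mus <- vapply(cache, function(ci) {
    p_b <- pet_percentile(ci$body_values, grid_b)
    den <- p_b - ci$p_alpha
    if (any(den <= 0))
      stop("degenerate landmark set: p_b <= p_alpha on the search grid")
    s_max * (ci$organ_mu - ci$p_alpha) / den
  }, numeric(length(grid_b)))
  if (is.null(dim(mus))) mus <- matrix(mus, nrow = 1L)  # single grid point
  delta <- apply(mus, 1L, function(row) sd_conv(row, sd_convention) / mean(row))

  dmin <- min(delta)
  # ties at the numerical-noise level collapse onto the largest b
  tie_tol <- 1e-12 + 1e-8 * dmin
  ties <- which(delta <= dmin + tie_tol)
  pick <- ties[length(ties)]
  structure(
    list(grid = data.frame(b = grid_b, delta = delta),
         beta = grid_b[pick], delta_at_beta = delta[pick]),
    class = "beta_search"
  )
}

#' @export
print.beta_search <- function(x, ...) {
  cat(sprintf("<beta_search> beta = %.1f, delta(beta) = %.6g over %d grid points in [%g, %g]\n",
              x$beta, x$delta_at_beta, nrow(x$grid), min(x$grid$b), max(x$grid$b)))
  invisible(x)
}

#' Standard-scale median landmark
#'
#' The cohort mean of the linearly mapped body medians: each image's
#' \[p_alpha(I), p_beta(I)\] is mapped onto \[0, s_max\] and the mapped
#' position of the body median p_m(I) is averaged over the cohort.
#'
#' @inheritParams delta_cv
#' @param beta The calibrated upper percentile.
#' @return The landmark s_m, with 0 < s_m < s_max for non-degenerate cohorts.
#' @export
estimate_sm <- function(cohort, beta, s_max) {
  if (length(cohort) < 1L) stop("empty calibration cohort")
  cache <- cohort_landmark_cache(cohort)
  vals <- vapply(cache, function(ci) {
    p_b <- pet_percentile(ci$body_values, beta)
    den <- p_b - ci$p_alpha
    if (den <= 0 || ci$p_m <= ci$p_alpha || ci$p_m >= p_b)
      stop("degenerate landmark set (p_alpha=", ci$p_alpha,
           ", p_m=", ci$p_m, ", p_beta=", p_b, ")")
    s_max * (ci$p_m - ci$p_alpha) / den
  }, numeric(1))
  mean(vals)
}

#' Inverse scale factor
#'
#' With p_alpha(I) = 0 the calibration map lambda is a pure multiplication by
#' f_I = s_max / p_beta(I). The inverse scale factor is the reciprocal of the
#' trimmed mean of those factors: factors more than one standard deviation
#' from their mean are removed first (if trimming removes everything, the
#' untrimmed mean is used). Multiplying standardized intensities by this
#' factor returns them to the physical scale of the calibration data.
#'
#' @inheritParams estimate_sm
#' @param sd_convention SD convention for the trim threshold.
#' @return The inverse scale factor (positive).
#' @export
estimate_inv_scale <- function(cohort, beta, s_max,
                               sd_convention = "population") {
  if (length(cohort) < 2L)
    stop("estimate_inv_scale needs a cohort of at least 2 images")
  cache <- cohort_landmark_cache(cohort)
  f <- vapply(cache, function(ci) {
    p_b <- pet_percentile(ci$body_values, beta)
    den <- p_b - ci$p_alpha
    if (den <= 0)
      stop("degenerate landmark set: p_beta <= p_alpha")
    s_max / den
  }, numeric(1))
  keep <- abs(f - mean(f)) <= sd_conv(f, sd_convention)
  retained <- if (any(keep)) f[keep] else f
  1 / mean(retained)
}

#' One-time calibration of the standard scale
#'
#' Runs the full calibration on a cohort of normal images of one modality:
#' the upper-percentile search ([optimize_beta()]), the standard median
#' landmark ([estimate_sm()]) at the optimum, and the inverse scale factor
#' ([estimate_inv_scale()]). The result is the sole hand-off to the
#' per-image transformation step; reference-organ masks are needed here and
#' never again.
#'
#' @param cohort List of [pet_volume()]s, all of one modality.
#' @param organ_masks Reference-organ masks aligned 1:1 with the cohort.
#' @param config A [std_config()]; its modality must match the cohort.
#' @return An object of class `standard_scale` with fields `s_min` (0),
#'   `s_m`, `s_max`, `beta`, `inv_scale`, `modality`, `calibration_n`,
#'   `reference_organ`, `created`, and the search `grid`.
#' @export
calibrate <- function(cohort, organ_masks, config = std_config()) {
  stopifnot(inherits(config, "std_config"))
  if (length(cohort) < 2L)
    stop("calibration needs at least 2 images")
  mods <- vapply(cohort, function(v) base_modality(v$modality), character(1))
  if (length(unique(mods)) != 1L)
    stop("cohort mixes modalities: ", paste(unique(mods), collapse = ", "))
  if (mods[1] != config$modality)
    stop("config modality (", config$modality,
         ") does not match cohort modality (", mods[1], ")")
  bs <- optimize_beta(cohort, organ_masks,
                      b_low = config$b_low, b_high = config$b_high,
                      step = config$b_step, s_max = config$s_max,
                      sd_convention = config$sd_convention)
  s_m <- estimate_sm(cohort, bs$beta, config$s_max)
  inv <- estimate_inv_scale(cohort, bs$beta, config$s_max,
                            sd_convention = config$sd_convention)
  standard_scale(s_m = s_m, s_max = config$s_max, beta = bs$beta,
                 inv_scale = inv, modality = config$modality,
                 calibration_n = length(cohort),
                 reference_organ = config$reference_organ,
                 grid = bs$grid)
}

#' Construct a standard scale object
#'
#' @param s_m Standard median landmark, 0 < s_m < s_max.
#' @param s_max Standard-scale ceiling.
#' @param beta Calibrated upper percentile in \[90, 100\].
#' @param inv_scale Inverse scale factor, positive.
#' @param modality `"AC"` or `"SUV"`.
#' @param calibration_n Number of calibration images.
#' @param reference_organ Reference organ name.
#' @param created ISO timestamp (defaults to now).
#' @param grid Optional percentile-search grid (data.frame of b, delta).
#' @return An object of class `standard_scale`.
#' @export
standard_scale <- function(s_m, s_max, beta, inv_scale, modality,
                           calibration_n = NA_integer_,
                           reference_organ = "liver",
                           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                           grid = NULL) {
  if (!(0 < s_m && s_m < s_max))
    stop("need 0 < s_m < s_max (got s_m=", s_m, ", s_max=", s_max, ")")
  if (beta < 90 || beta > 100)
    stop("beta must lie in [90, 100]")
  if (inv_scale <= 0)
    stop("inv_scale must be positive")
  modality <- match.arg(modality, c("AC", "SUV"))
  structure(
    list(s_min = 0, s_m = s_m, s_max = s_max, beta = beta,
         inv_scale = inv_scale, modality = modality,
         calibration_n = as.integer(calibration_n),
         reference_organ = reference_organ, created = created, grid = grid),
    class = "standard_scale"
  )
}

#' @export
print.standard_scale <- function(x, ...) {
  cat(sprintf(
    "<standard_scale> %s  s = [0, %g, %g]  beta = %.1f  inv_scale = %.6g  (n = %d, organ = %s)\n",
    x$modality, x$s_m, x$s_max, x$beta, x$inv_scale,
    x$calibration_n, x$reference_organ))
  invisible(x)
}

#' Serialize / deserialize a standard scale as JSON
#'
#' The JSON file is the complete hand-off from calibration to transformation;
#' the search grid is not embedded (persist it separately as CSV if an audit
#' trail is wanted, see [cli_calibrate()]).
#'
#' @param scale A `standard_scale`.
#' @param path File path.
#' @return `write_scale` invisibly returns `path`; `read_scale` returns a
#'   `standard_scale`.
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "standard_scale"))
  jsonlite::write_json(
    scale[c("modality", "s_min", "s_m", "s_max", "beta", "inv_scale",
            "calibration_n", "reference_organ", "created")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale
#' @export
read_scale <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  standard_scale(s_m = x$s_m, s_max = x$s_max, beta = x$beta,
                 inv_scale = x$inv_scale, modality = x$modality,
                 calibration_n = x$calibration_n,
                 reference_organ = x$reference_organ, created = x$created)
}
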