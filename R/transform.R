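# -- Transformation: per-image piecewise-linear standardization --------------

#' Piecewise-linear mapping specification
#'
#' Pairs the landmarks of an input image with a calibrated [standard_scale()]
#' and derives the two segment slopes of the intermediate mapping eta:
#' \[p_alpha, p_m\] -> \[s_min, s_m\] and \[p_m, p_beta\] -> \[s_m, s_max\].
#' Both segments extrapolate linearly beyond their landmark interval, so the
#' full dynamic range of the input (including the high-uptake tail above
#' p_beta) is retained; the image maximum maps to an image-specific value
#' above s_max. Requires strictly ordered landmarks (positive slopes).
#'
#' @param landmarks A [landmark_set()] of the input image, extracted at
#'   `scale$beta`.
#' @param scale A [standard_scale()].
#' @return An object of class `mapping_spec` with the landmarks, scale and
#'   slopes `slope1`, `slope2`.
#' @export
mapping_spec <- function(landmarks, scale) {
  stopifnot(inherits(landmarks, "landmark_set"),
            inherits(scale, "standard_scale"))
  if (isTRUE(landmarks$degenerate))
    stop("degenerate landmark set cannot define a standardization mapping")
  slope1 <- (scale$s_m - scale$s_min) / (landmarks$p_m - landmarks$p_alpha)
  slope2 <- (scale$s_max - scale$s_m) / (landmarks$p_beta - landmarks$p_m)
  if (!(slope1 > 0) || !(slope2 > 0))
    stop("mapping slopes must be positive; landmarks are not strictly ordered")
  structure(list(landmarks = landmarks, scale = scale,
                 slope1 = slope1, slope2 = slope2),
            class = "mapping_spec")
}

#' Intermediate standardization mapping
#'
#' Evaluates the continuous, strictly increasing two-segment map eta at
#' intensities `x`: below the body median the first segment (through
#' (p_alpha, s_min) and (p_m, s_m)) applies, above it the second (through
#' (p_m, s_m) and (p_beta, s_max)); both tails extrapolate linearly.
#'
#' @param x Numeric vector of input intensities.
#' @param spec A [mapping_spec()].
#' @return Mapped intensities, same length as `x`.
#' @export
eta <- function(x, spec) {
  stopifnot(inherits(spec, "mapping_spec"))
  lm <- spec$landmarks
  sc <- spec$scale
  lower <- x <= lm$p_m
  out <- numeric(length(x))
  out[lower] <- sc$s_min + spec$slope1 * (x[lower] - lm$p_alpha)
  out[!lower] <- sc$s_m + spec$slope2 * (x[!lower] - lm$p_m)
  out
}

#' Standardize a PET volume
#'
#' Applies the full standardization mapping psi = inv_scale * eta voxel-wise:
#' the image's own landmarks (body-region median and upper percentile at the
#' calibrated beta) are matched to the standard scale piecewise linearly, and
#' the inverse scale factor restores physical intensity meaning. Only the
#' automatic body mask of the input is needed — no organ segmentation. The
#' map is strictly increasing, so voxel rank order is preserved exactly.
#'
#' @param volume A [pet_volume()] whose base modality matches the scale.
#' @param scale A [standard_scale()].
#' @param landmarks Optional precomputed [landmark_set()] (must have been
#'   extracted at `scale$beta`).
#' @return A [pet_volume()] of modality `STD_AC` or `STD_SUV`.
#' @export
standardize <- function(volume, scale, landmarks = NULL) {
  stopifnot(inherits(volume, "pet_volume"), inherits(scale, "standard_scale"))
  if (base_modality(volume$modality) != scale$modality)
    stop("modality mismatch: volume is ", volume$modality,
         " but the scale was calibrated for ", scale$modality)
  if (is.null(landmarks)) {
    landmarks <- extract_landmarks(volume, beta = scale$beta)
  } else if (abs(landmarks$beta - scale$beta) > 1e-9) {
    stop("landmarks were extracted at beta = ", landmarks$beta,
         " but the scale uses beta = ", scale$beta)
  }
  spec <- mapping_spec(landmarks, scale)
  out <- scale$inv_scale * eta(as.vector(volume$voxels), spec)
  if (any(out < 0))
    stop("standardization produced negative intensities; ",
         "input violates the p_alpha = min(I) = 0 assumption")
  pet_volume(array(out, dim = dim(volume$voxels)), spacing = volume$spacing,
             modality = paste0("STD_", scale$modality),
             units = volume$units)
}

#' Run a chained standardization strategy
#'
#' Executes an ordered chain of steps from `{"s-AC", "SUV", "s-SUV"}` left to
#' right: `"s-AC"` standardizes AC volumes, `"SUV"` converts AC to SUV via
#' the dose/weight formula, `"s-SUV"` standardizes SUV volumes. Every
#' standardization step calibrates on the calibration cohort *as transformed
#' by the preceding steps* — in particular a repeated standardization
#' re-estimates the calibration parameters on the already-standardized
#' calibration set (e.g. `"s-SUV,s-SUV"`).
#'
#' @param steps Character vector of step tokens, or a single comma-separated
#'   string such as `"s-AC,SUV,s-SUV"`.
#' @param images List of input [pet_volume()]s (the test set).
#' @param metas List of [scan_meta()] aligned with `images` (needed iff the
#'   chain contains `"SUV"`).
#' @param calib List of calibration-cohort [pet_volume()]s.
#' @param calib_metas List of [scan_meta()] for the calibration cohort.
#' @param organ_masks Reference-organ masks for the calibration cohort.
#' @param b_low,b_high,b_step Percentile-search parameters.
#' @param sd_convention SD convention.
#' @param s_max_ac,s_max_suv Standard-scale ceilings per modality.
#' @return A list with `images` (transformed test images), `calib` (the
#'   transformed calibration cohort) and `scales` (one [standard_scale()] per
#'   standardization step, in order).
#' @export
run_strategy <- function(steps, images, metas = NULL,
                         calib, calib_metas = NULL, organ_masks,
                         b_low = 90, b_high = 100, b_step = 0.1,
                         sd_convention = "population",
                         s_max_ac = 50000, s_max_suv = 5.00) {
  if (length(steps) == 1L && grepl(",", steps))
    steps <- trimws(strsplit(steps, ",")[[1]])
  ok <- c("s-AC", "SUV", "s-SUV")
  if (length(steps) == 0L || !all(steps %in% ok))
    stop("strategy steps must come from {", paste(ok, collapse = ", "), "}")
  scales <- list()
  for (step in steps) {
    cur_mod <- base_modality(images[[1]]$modality)
    if (step == "SUV") {
      if (cur_mod != "AC")
        stop("ill-typed chain: SUV conversion applied to ", cur_mod, " images")
      if (is.null(metas) || is.null(calib_metas))
        stop("SUV step requires scan metadata for images and calibration cohort")
      images <- Map(ac_to_suv, images, metas)
      calib <- Map(ac_to_suv, calib, calib_metas)
    } else {
      want <- if (step == "s-AC") "AC" else "SUV"
      if (cur_mod != want)
        stop("ill-typed chain: ", step, " applied to ", cur_mod, " images")
      cfg <- std_config(modality = want,
                        s_max = if (want == "AC") s_max_ac else s_max_suv,
                        b_low = b_low, b_high = b_high, b_step = b_step,
                        sd_convention = sd_convention)
      scale <- calibrate(calib, organ_masks, cfg)
      scales[[length(scales) + 1L]] <- scale
      images <- lapply(images, standardize, scale = scale)
      calib <- lapply(calib, standardize, scale = scale)
    }
  }
  list(images = images, calib = calib, scales = scales)
}
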