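#' Threshold a PET volume at its mean to obtain the body region
#'
#' Whole-torso PET histograms are bimodal: a large near-zero background mode
#' (air outside the body) and a body mode. Thresholding at the global mean
#' intensity separates the two; voxels strictly greater than `mean(I)` form
#' the body mask. The body-median landmark downstream is insensitive to the
#' imprecision of this rough segmentation.
#'
#' @param volume A [pet_volume()] with at least two distinct values.
#' @return A [pet_mask()] of kind `"body"`.
#' @export
body_mask <- function(volume) {
  stopifnot(inherits(volume, "pet_volume"))
  v <- volume$voxels
  m <- mean(v)
  sel <- v > m
  if (!any(sel))
    stop("degenerate input: volume is constant, body mask would be empty")
  pet_mask(array(sel, dim = dim(v)), kind = "body")
}

#' Linear-interpolation percentile
#'
#' The q-th percentile of a multiset of intensities under linear interpolation
#' between order statistics (the inclusive scheme): the value at fractional
#' rank h = (n-1) q/100 + 1 of the sorted data. Continuous in q (which the
#' percentile grid search requires), with q = 0 giving the minimum, q = 100
#' the maximum, and q = 50 the median.
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile(s) in \[0, 100\].
#' @return Percentile value(s).
#' @export
pet_percentile <- function(values, q) {
  if (length(values) == 0L)
    stop("cannot take a percentile of an empty set")
  if (any(q < 0) || any(q > 100))
    stop("percentile must lie in [0, 100]")
  stats::quantile(values, probs = q / 100, type = 7, names = FALSE)
}

#' Per-image intensity landmark set
#'
#' The five landmarks anchoring the standardization mapping of an image I:
#' `i_min = min(I)`, the lower percentile `p_alpha` (pinned to `min(I)`,
#' which is essentially always 0 in PET), the body-region median `p_m`, the
#' upper percentile `p_beta` at percentile `beta` of the body-region voxels,
#' and `i_max = max(I)`. A valid standardization mapping needs the strict
#' ordering `p_alpha < p_m < p_beta`.
#'
#' @param volume A [pet_volume()].
#' @param beta Upper percentile in (0, 100\].
#' @param body Optional precomputed body [pet_mask()] (computed from the
#'   volume if omitted).
#' @param strict If `TRUE` (default) a degenerate ordering is an error;
#'   otherwise the returned set carries `degenerate = TRUE`.
#' @return An object of class `landmark_set` with fields `i_min`, `p_alpha`,
#'   `p_m`, `p_beta`, `i_max`, `alpha`, `beta`, `degenerate`.
#' @export
extract_landmarks <- function(volume, beta, body = NULL, strict = TRUE) {
  stopifnot(inherits(volume, "pet_volume"))
  if (length(beta) != 1L || beta <= 0 || beta > 100)
    stop("beta must be a single percentile in (0, 100]")
  if (is.null(body)) body <- body_mask(volume)
  check_aligned(volume, body)
  v <- volume$voxels
  bv <- v[body$voxels]
  lm <- landmark_set(
    i_min = min(v),
    p_alpha = min(v),  # alpha pinned to the volume minimum
    p_m = pet_percentile(bv, 50),
    p_beta = pet_percentile(bv, beta),
    i_max = max(v),
    alpha = 0,
    beta = beta,
    strict = strict
  )
  lm
}

#' @rdname extract_landmarks
#' @param i_min,p_alpha,p_m,p_beta,i_max Landmark intensities.
#' @param alpha Percentile that produced `p_alpha` (0 when pinned to the
#'   minimum).
#' @export
landmark_set <- function(i_min, p_alpha, p_m, p_beta, i_max,
                         alpha = 0, beta, strict = TRUE) {
  if (!(i_min <= p_alpha && p_alpha <= p_m && p_m <= p_beta && p_beta <= i_max))
    stop("landmarks violate the ordering i_min <= p_alpha <= p_m <= p_beta <= i_max")
  degenerate <- !(p_alpha < p_m && p_m < p_beta)
  if (degenerate && strict)
    stop("degenerate landmark set: need p_alpha < p_m < p_beta ",
         sprintf("(got p_alpha=%g, p_m=%g, p_beta=%g)", p_alpha, p_m, p_beta))
  structure(
    list(i_min = i_min, p_alpha = p_alpha, p_m = p_m, p_beta = p_beta,
         i_max = i_max, alpha = alpha, beta = beta, degenerate = degenerate),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set> min=%g p_alpha=%g p_m=%g p_beta=%g max=%g (alpha=%g, beta=%g)%s\n",
    x$i_min, x$p_alpha, x$p_m, x$p_beta, x$i_max, x$alpha, x$beta,
    if (isTRUE(x$degenerate)) "  [DEGENERATE]" else ""))
  invisible(x)
}

#' Serialize / deserialize a landmark set as JSON
#'
#' @param lm A `landmark_set`.
#' @param path File path.
#' @return `write_landmarks` invisibly returns `path`; `read_landmarks`
#'   returns a `landmark_set`.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  jsonlite::write_json(
    lm[c("i_min", "p_alpha", "p_m", "p_beta", "i_max", "alpha", "beta")],
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(i_min = x$i_min, p_alpha = x$p_alpha, p_m = x$p_m,
               p_beta = x$p_beta, i_max = x$i_max,
               alpha = x$alpha, beta = x$beta, strict = FALSE)
}
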