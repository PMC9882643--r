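# -- Synthetic body-torso phantom cohorts ------------------------------------
#
# The generator emulates the statistical structure the standardization method
# rests on, not anatomy: a near-zero background mode, a roughly unimodal body
# region, homogeneous liver/spleen regions with between-subject biological
# variability, sparse very-high-uptake lesion foci whose values are chaotic
# across subjects, one multiplicative per-scan scanner gain, and
# mean-proportional Gaussian noise. Ellipsoids suffice because the method
# sees only histograms and masks.

#' Phantom cohort configuration
#'
#' Default levels are on the AC (Bq/mL) scale and sit inside the normal-scan
#' ranges typical of body-torso FDG PET: soft-tissue body at 2000 Bq/mL,
#' liver 6000, spleen 5000, lesion foci 20,000-50,000. Between-subject organ
#' variability (5% CV), a wide scanner gain range (0.5-2.0) and a 2% lesion
#' load define the study conditions for the package's experiments. Lesions
#' are deliberately the only gain-independent cross-subject chaos: they are
#' exactly the phenomenon the upper-percentile optimization exists to excise.
#'
#' @param grid_shape Integer length-3 grid dimensions (nz, ny, nx).
#' @param spacing Voxel spacing in mm.
#' @param background_level Background intensity (~0).
#' @param body_level Soft-tissue intensity.
#' @param organ_levels Named vector of organ mean intensities (liver,
#'   spleen), all above `body_level`.
#' @param organ_cv_between_subjects CV of the per-subject multiplicative
#'   organ factors (true biological variability).
#' @param gain_range Range of the per-scan multiplicative scanner gain.
#' @param lesion_fraction Fraction of body voxels occupied by lesion foci,
#'   in \[0, 0.1) so lesions stay in the upper-percentile tail.
#' @param lesion_level_range Range of per-focus intensities, above every
#'   organ level.
#' @param noise_sigma_fraction Gaussian noise SD as a fraction of the local
#'   noise-free value.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(24, 32, 32),
                           spacing = c(4, 4, 4),
                           background_level = 0,
                           body_level = 2000,
                           organ_levels = c(liver = 6000, spleen = 5000),
                           organ_cv_between_subjects = 0.05,
                           gain_range = c(0.5, 2.0),
                           lesion_fraction = 0.02,
                           lesion_level_range = c(20000, 50000),
                           noise_sigma_fraction = 0.05) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be 3 integers, each >= 8")
  if (background_level < 0 || background_level >= body_level)
    stop("need 0 <= background_level < body_level")
  if (is.null(names(organ_levels)) || !all(c("liver", "spleen") %in% names(organ_levels)))
    stop("organ_levels must name liver and spleen")
  if (any(organ_levels <= body_level))
    stop("organ levels must exceed body_level")
  if (lesion_fraction < 0 || lesion_fraction >= 0.1)
    stop("lesion_fraction must lie in [0, 0.1): lesions must stay in the upper tail")
  if (lesion_level_range[1] <= max(organ_levels))
    stop("lesion_level_range must start above the highest organ level")
  if (lesion_level_range[1] > lesion_level_range[2])
    stop("lesion_level_range must be increasing")
  if (gain_range[1] <= 0 || gain_range[1] > gain_range[2])
    stop("gain_range must be positive and increasing")
  if (organ_cv_between_subjects < 0 || noise_sigma_fraction < 0)
    stop("variability parameters must be non-negative")
  structure(
    list(grid_shape = grid_shape, spacing = spacing,
         background_level = background_level, body_level = body_level,
         organ_levels = organ_levels,
         organ_cv_between_subjects = organ_cv_between_subjects,
         gain_range = gain_range, lesion_fraction = lesion_fraction,
         lesion_level_range = lesion_level_range,
         noise_sigma_fraction = noise_sigma_fraction),
    class = "phantom_config"
  )
}

# logical ellipsoid on a (nz, ny, nx) grid; center/semi in voxel units
ellipsoid_mask <- function(dim, center, semi) {
  z <- (seq_len(dim[1]) - center[1]) / semi[1]
  y <- (seq_len(dim[2]) - center[2]) / semi[2]
  x <- (seq_len(dim[3]) - center[3]) / semi[3]
  d2 <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  d2 <= 1
}

# fixed phantom geometry: one body ellipsoid, liver and spleen inside it
phantom_geometry <- function(config) {
  d <- config$grid_shape
  c0 <- (d + 1) / 2
  body <- ellipsoid_mask(d, c0, 0.42 * d)
  liver <- ellipsoid_mask(d, c0 + c(0, -0.09 * d[2], -0.12 * d[3]), 0.19 * d) & body
  spleen <- ellipsoid_mask(d, c0 + c(0, -0.09 * d[2], 0.19 * d[3]),
                           c(0.125, 0.11, 0.11) * d) & body
  spleen <- spleen & !liver
  list(body = body, liver = liver, spleen = spleen)
}

# draws consuming the current RNG stream: per-subject organ factors and
# sparse lesion foci (positions + per-focus levels)
draw_biology <- function(config, geom) {
  organs <- names(config$organ_levels)
  factors <- stats::rnorm(length(organs), mean = 1,
                          sd = config$organ_cv_between_subjects)
  factors <- pmax(factors, 0.2)  # guard against absurd draws at high CV
  names(factors) <- organs

  eligible <- geom$body & !geom$liver & !geom$spleen
  n_target <- round(config$lesion_fraction * sum(geom$body))
  lesion_idx <- integer(0)
  lesion_val <- numeric(0)
  d <- config$grid_shape
  if (n_target > 0) {
    elig_idx <- which(eligible)
    coords <- arrayInd(elig_idx, d)
    taken <- logical(length(elig_idx))
    guard <- 0L
    while (length(lesion_idx) < n_target && guard < 1000L) {
      guard <- guard + 1L
      free <- which(!taken)
      if (length(free) == 0L) break
      ci <- free[sample.int(length(free), 1L)]
      r <- stats::runif(1, 1.2, 2.2)
      dist2 <- (coords[, 1] - coords[ci, 1])^2 +
               (coords[, 2] - coords[ci, 2])^2 +
               (coords[, 3] - coords[ci, 3])^2
      blob <- which(dist2 <= r^2 & !taken)
      if (length(blob) == 0L) next
      need <- n_target - length(lesion_idx)
      if (length(blob) > need) blob <- blob[seq_len(need)]
      taken[blob] <- TRUE
      lesion_idx <- c(lesion_idx, elig_idx[blob])
      lesion_val <- c(lesion_val,
                      rep(stats::runif(1, config$lesion_level_range[1],
                                       config$lesion_level_range[2]),
                          length(blob)))
    }
  }
  list(factors = factors, lesion_idx = lesion_idx, lesion_val = lesion_val)
}

# assemble the noise-free phantom, apply gain, then mean-proportional noise
# (consumes the current RNG stream for the noise draw)
render_phantom <- function(config, geom, biology, gain) {
  d <- config$grid_shape
  ideal <- array(config$background_level, dim = d)
  ideal[geom$body] <- config$body_level
  ideal[geom$liver] <- config$organ_levels[["liver"]] * biology$factors[["liver"]]
  ideal[geom$spleen] <- config$organ_levels[["spleen"]] * biology$factors[["spleen"]]
  if (length(biology$lesion_idx))
    ideal[biology$lesion_idx] <- biology$lesion_val
  ideal <- ideal * gain
  if (config$noise_sigma_fraction > 0) {
    noisy <- ideal * (1 + config$noise_sigma_fraction * stats::rnorm(length(ideal)))
    ideal <- array(pmax(noisy, 0), dim = d)
  }
  pet_volume(ideal, spacing = config$spacing, modality = "AC")
}

# package one subject: volume + ground-truth masks + truth record
assemble_subject <- function(config, geom, biology, gain, subject_seed) {
  vol <- render_phantom(config, geom, biology, gain)
  d <- config$grid_shape
  lesion_mask <- array(FALSE, dim = d)
  lesion_mask[biology$lesion_idx] <- TRUE
  masks <- list(
    body = pet_mask(geom$body, "body"),
    liver = pet_mask(geom$liver & !lesion_mask, "liver"),
    spleen = pet_mask(geom$spleen & !lesion_mask, "spleen"),
    lesion = pet_mask(lesion_mask, "lesion")
  )
  truth <- list(
    subject_seed = subject_seed,
    gain = gain,
    organ_factors = as.list(biology$factors),
    organ_means_true = as.list(gain * config$organ_levels *
                               unlist(biology$factors[names(config$organ_levels)])),
    body_level_scanned = gain * config$body_level,
    n_lesion_voxels = length(biology$lesion_idx),
    lesion_onset_pct = 100 * (1 - length(biology$lesion_idx) / sum(geom$body))
  )
  list(volume = vol, masks = masks, truth = truth)
}

#' Generate one synthetic phantom scan
#'
#' Deterministic given `(config, subject_seed)`. Returns the scan together
#' with ground-truth masks (body, liver, spleen — organ masks exclude any
#' lesion voxels — and lesion) and a truth record (drawn gain, organ factors,
#' true organ means, lesion onset percentile) sufficient to compute every
#' ground-truth quantity without re-reading the voxels.
#'
#' @param config A [phantom_config()].
#' @param subject_seed Integer seed for this subject.
#' @return A list with `volume`, `masks`, `truth`.
#' @export
generate_phantom <- function(config = phantom_config(), subject_seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  geom <- phantom_geometry(config)
  set.seed(subject_seed)
  biology <- draw_biology(config, geom)
  gain <- stats::runif(1, config$gain_range[1], config$gain_range[2])
  assemble_subject(config, geom, biology, gain, subject_seed)
}

#' Generate a cohort of independent phantom subjects
#'
#' Subject seeds are derived deterministically from the master seed; each
#' subject draws its own organ factors, lesions, gain and noise. Scan
#' metadata (dose ~ U(480, 620) MBq, weight ~ U(55, 95) kg) is attached per
#' subject for SUV conversion.
#'
#' @param config A [phantom_config()].
#' @param n Number of subjects (>= 2).
#' @param seed Master seed.
#' @return A list of subjects, each as in [generate_phantom()] plus a
#'   `meta` ([scan_meta()]) entry.
#' @export
generate_cohort <- function(config = phantom_config(), n = 10, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"), n >= 2)
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max, n)
  doses <- stats::runif(n, 480, 620)
  weights <- stats::runif(n, 55000, 95000)
  scanners <- rep("sim-scanner", n)
  lapply(seq_len(n), function(i) {
    subj <- generate_phantom(config, subject_seeds[i])
    subj$meta <- scan_meta(doses[i], weights[i],
                           subject_id = sprintf("sub-%02d", i),
                           scanner_id = scanners[i])
    subj
  })
}

#' Generate repeat-scan pairs
#'
#' Each pair shares subject anatomy, lesions and organ factors up to a small
#' multiplicative biological jitter (each organ factor of the second scan is
#' the first scan's factor times 1 + U(-jitter, +jitter)), but draws an
#' independent scanner gain and independent noise — the test-retest setting
#' in which raw organ means disagree through gain while standardized means
#' agree up to biology.
#'
#' @param config A [phantom_config()].
#' @param n_pairs Number of subjects/pairs.
#' @param seed Master seed.
#' @param repeat_jitter Maximum relative biological change between the two
#'   scans (>= 0).
#' @return A list of pairs; each pair is a list with `scan1`, `scan2` (each
#'   as in [generate_phantom()] with `meta`).
#' @export
generate_repeat_pairs <- function(config = phantom_config(), n_pairs = 10,
                                  seed = 1L, repeat_jitter = 0.03) {
  stopifnot(inherits(config, "phantom_config"), repeat_jitter >= 0)
  geom <- phantom_geometry(config)
  set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max, n_pairs)
  doses <- stats::runif(n_pairs, 480, 620)
  weights <- stats::runif(n_pairs, 55000, 95000)
  dose_jitter <- stats::runif(n_pairs, -0.05, 0.05)
  lapply(seq_len(n_pairs), function(i) {
    set.seed(pair_seeds[i])
    biology <- draw_biology(config, geom)
    gain1 <- stats::runif(1, config$gain_range[1], config$gain_range[2])
    scan1 <- assemble_subject(config, geom, biology, gain1, pair_seeds[i])
    biology2 <- biology
    biology2$factors <- biology$factors *
      (1 + stats::runif(length(biology$factors), -repeat_jitter, repeat_jitter))
    gain2 <- stats::runif(1, config$gain_range[1], config$gain_range[2])
    scan2 <- assemble_subject(config, geom, biology2, gain2, pair_seeds[i])
    scan1$meta <- scan_meta(doses[i], weights[i],
                            subject_id = sprintf("sub-%02d", i),
                            scanner_id = "sim-scanner")
    scan2$meta <- scan_meta(doses[i] * (1 + dose_jitter[i]), weights[i],
                            subject_id = sprintf("sub-%02d", i),
                            scanner_id = "sim-scanner")
    list(scan1 = scan1, scan2 = scan2)
  })
}

#' Convert a generated AC subject to SUV
#'
#' Applies [ac_to_suv()] to the subject's volume using its attached metadata
#' and rescales the truth-record organ means accordingly.
#'
#' @param subject A subject from [generate_cohort()] (or one scan of a
#'   repeat pair, with `meta` attached).
#' @return The subject with an SUV volume and converted truth means.
#' @export
subject_to_suv <- function(subject) {
  stopifnot(!is.null(subject$meta))
  k <- 1e-6 / (subject$meta$injected_dose / subject$meta$body_weight)
  subject$volume <- ac_to_suv(subject$volume, subject$meta)
  subject$truth$organ_means_true <- lapply(subject$truth$organ_means_true,
                                           function(x) x * k)
  subject$truth$body_level_scanned <- subject$truth$body_level_scanned * k
  subject
}
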