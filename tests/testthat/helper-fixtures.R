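# In-code fixtures shared across test files.

# wrap a plain array (or vector + dims) as an AC volume
make_vol <- function(values, dims = NULL, modality = "AC") {
  if (is.null(dims)) dims <- dim(values)
  pet_volume(array(values, dim = dims), modality = modality)
}

# a 4x4x4 volume: zero background with selected voxels set
sparse_vol <- function(values, modality = "AC") {
  a <- array(0, dim = c(4, 4, 4))
  a[seq_along(values)] <- values
  pet_volume(a, modality = modality)
}

# full-volume mask over given linear indices
mask_at <- function(dims, idx, kind = "other") {
  m <- array(FALSE, dim = dims)
  m[idx] <- TRUE
  pet_mask(m, kind)
}

# small phantom configuration used by unit tests (fast, same structure)
test_config <- function(...) {
  phantom_config(grid_shape = c(16, 20, 20), ...)
}

# convenience extractors for generated subjects
cohort_volumes <- function(cohort) lapply(cohort, `[[`, "volume")
cohort_masks <- function(cohort, organ) lapply(cohort, function(s) s$masks[[organ]])
cohort_organ_means <- function(cohort, organ) {
  mapply(function(s) organ_mean(s$volume, s$masks[[organ]]), cohort)
}

# 6-neighbourhood erosion of a logical 3D array (for robustness checks)
erode_once <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(arr, axis, by) {
    res <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    rng <- seq_len(d[axis] - abs(by))
    idx_src[[axis]] <- if (by > 0) rng else rng + abs(by)
    idx_dst[[axis]] <- if (by > 0) rng + by else rng
    res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    res
  }
  for (axis in 1:3)
    for (by in c(-1, 1))
      out <- out & shift(m, axis, by)
  out
}
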