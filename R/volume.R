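#' PET volume objects
#'
#' A `pet_volume` is a 3D scalar grid of non-negative, finite voxel values
#' with voxel spacing in mm and a modality tag. Activity-concentration (AC)
#' volumes carry values in Bq/mL; SUV volumes are unitless; `STD_AC` and
#' `STD_SUV` tag standardized outputs.
#'
#' @param voxels 3D numeric array of non-negative, finite values.
#' @param spacing Numeric length-3 vector of voxel spacing in mm, one entry
#'   per array dimension, all strictly positive.
#' @param modality One of `"AC"`, `"SUV"`, `"STD_AC"`, `"STD_SUV"`.
#' @param units Units string; defaults to `"Bq/mL"` for AC-family volumes and
#'   `""` (unitless) otherwise.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(voxels, spacing = c(1, 1, 1),
                       modality = c("AC", "SUV", "STD_AC", "STD_SUV"),
                       units = NULL) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (!is.numeric(voxels))
    stop("voxels must be numeric")
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels)))
    stop("voxels must be finite (NaN/Inf not allowed)")
  if (any(voxels < 0))
    stop("negative voxel values are not allowed (PET activity is non-negative)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (is.null(units))
    units <- if (modality %in% c("AC", "STD_AC")) "Bq/mL" else ""
  structure(
    list(voxels = voxels, spacing = spacing, modality = modality, units = units),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<pet_volume> %s  %dx%dx%d voxels  spacing %s mm  range [%g, %g] %s\n",
              x$modality, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = "x"),
              min(x$voxels), max(x$voxels), x$units))
  invisible(x)
}

#' Strip the standardized prefix from a modality tag
#'
#' `"STD_AC"` and `"AC"` both live on the AC intensity scale; chained
#' operations (SUV conversion, re-standardization) dispatch on this base tag.
#'
#' @param modality Modality string.
#' @return `"AC"` or `"SUV"`.
#' @export
base_modality <- function(modality) {
  sub("^STD_", "", modality)
}

#' Binary organ / body masks
#'
#' A `pet_mask` is a logical 3D grid aligned voxel-for-voxel with a companion
#' [pet_volume()].
#'
#' @param voxels 3D logical (or 0/1 numeric) array.
#' @param kind One of `"body"`, `"liver"`, `"spleen"`, `"lesion"`, `"other"`.
#' @return An object of class `pet_mask`.
#' @export
pet_mask <- function(voxels, kind = c("body", "liver", "spleen", "lesion", "other")) {
  kind <- match.arg(kind)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask voxels must form a 3D array")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("numeric masks must contain only 0/1")
    voxels <- array(voxels != 0, dim = dim(voxels))
  }
  if (!is.logical(voxels))
    stop("mask voxels must be logical or 0/1 numeric")
  structure(list(voxels = voxels, kind = kind), class = "pet_mask")
}

#' @export
print.pet_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<pet_mask> %s  %dx%dx%d  %d voxels set\n",
              x$kind, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

# shape agreement between a mask and its companion volume
check_aligned <- function(volume, mask, require_nonempty = TRUE) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "pet_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("mask grid shape does not match the volume")
  if (require_nonempty && !any(mask$voxels))
    stop("mask is empty; a reference region needs at least one voxel")
  invisible(TRUE)
}

#' Per-scan acquisition metadata
#'
#' Carries the two quantities needed for AC to SUV conversion: injected
#' radiotracer dose (MBq) and body weight (g). Under the usual 1 g/mL average
#' body mass density assumption, weight in grams equals body volume in mL,
#' which makes SUV unitless.
#'
#' @param injected_dose Injected dose in MBq, positive.
#' @param body_weight Body weight in g, positive.
#' @param subject_id,scanner_id Identifier strings.
#' @return An object of class `scan_meta`.
#' @export
scan_meta <- function(injected_dose, body_weight,
                      subject_id = "unknown", scanner_id = "unknown") {
  if (!is.numeric(injected_dose) || length(injected_dose) != 1L ||
      !is.finite(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be a single positive number (MBq)")
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("body_weight must be a single positive number (g)")
  structure(
    list(injected_dose = injected_dose, body_weight = body_weight,
         subject_id = as.character(subject_id),
         scanner_id = as.character(scanner_id)),
    class = "scan_meta"
  )
}

#' Read a PET volume from a NIfTI file
#'
#' @param path Path to a `.nii` / `.nii.gz` file holding a 3D scalar grid.
#' @param modality Modality tag to attach (the file format does not record it).
#' @return A [pet_volume()].
#' @export
read_volume <- function(path, modality = c("AC", "SUV", "STD_AC", "STD_SUV")) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("non-3D data in ", path, " (got ", length(dim(a)), " dimensions)")
  if (any(a < 0))
    stop("negative voxel values in ", path,
         "; PET activity is non-negative, refusing to load")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  pet_volume(array(as.double(a), dim = dim(a)), spacing = sp, modality = modality)
}

#' Write a PET volume to a NIfTI file
#'
#' Voxels are stored as 32-bit floats, which preserves clinical SUV
#' discriminability (0.01 SUV steps) and the full Bq/mL AC range with large
#' margin. Values exactly representable in float32 round-trip bit-exactly.
#'
#' @param volume A [pet_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  if (any(!is.finite(volume$voxels)))
    stop("volume contains non-finite values; refusing to write")
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("parent directory does not exist: ", dir)
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' @param path Path to a NIfTI file containing a 0/1 volume.
#' @param kind Mask kind, see [pet_mask()].
#' @return A [pet_mask()].
#' @export
read_mask <- function(path, kind = c("body", "liver", "spleen", "lesion", "other")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("file not found: ", path)
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 3L)
    stop("non-3D mask in ", path)
  if (!all(a %in% c(0, 1)))
    stop("mask file ", path, " is not 0/1")
  pet_mask(array(a != 0, dim = dim(a)), kind = kind)
}

#' Write a binary mask to a NIfTI file as a 0/1 volume
#'
#' @param mask A [pet_mask()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "pet_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim = dim(mask$voxels)))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Convert an AC volume to SUV
#'
#' SUV(v) = AC_MBq(v) / (injected dose / body weight), with AC stored in
#' Bq/mL and divided by 1e6 to obtain MBq/mL, dose in MBq and weight in g
#' (1 g/mL body density, so g = mL and SUV is unitless). The map is linear
#' and order-preserving in the input intensities.
#'
#' @param volume A [pet_volume()] of modality `AC` (or `STD_AC`, for
#'   SUV estimation downstream of AC standardization).
#' @param meta A [scan_meta()] with positive dose and weight.
#' @return A [pet_volume()] of modality `SUV`.
#' @export
ac_to_suv <- function(volume, meta) {
  stopifnot(inherits(volume, "pet_volume"), inherits(meta, "scan_meta"))
  if (base_modality(volume$modality) != "AC")
    stop("ac_to_suv expects an AC (or STD_AC) volume, got ", volume$modality)
  suv <- (volume$voxels * 1e-6) / (meta$injected_dose / meta$body_weight)
  pet_volume(suv, spacing = volume$spacing, modality = "SUV", units = "")
}
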