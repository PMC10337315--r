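#' PET volume and tumour mask containers
#'
#' A `pet_volume` wraps a 3D scalar grid together with its voxel spacing
#' (mm), world origin (mm) and a units flag tracking the quantification
#' state: raw activity concentration (Bq/mL), standardised uptake value
#' (SUV, body-weight normalised), or glucose-corrected SUV. The units flag
#' may only move forward along `activity -> suv -> suv_glucose`.
#' A `tumour_mask` is a binary grid on the same lattice delineating the
#' primary-tumour region of interest.
#'
#' World coordinates follow `origin + index * spacing` with 0-based voxel
#' indices; a mask and its paired volume must share the grid exactly.
#'
#' @param values 3D numeric array.
#' @param spacing Numeric length-3 voxel spacing in mm, strictly positive.
#' @param origin Numeric length-3 world origin in mm.
#' @param units One of `"activity"`, `"suv"`, `"suv_glucose"`.
#' @return `pet_volume()` returns an object of class `pet_volume`;
#'   `tumour_mask()` returns an object of class `tumour_mask`.
#' @examples
#' vol <- pet_volume(array(1, c(4, 4, 2)), spacing = c(4, 4, 3))
#' msk <- tumour_mask(array(c(0, 1), c(4, 4, 2)), spacing = c(4, 4, 3))
#' @export
pet_volume <- function(values, spacing, origin = c(0, 0, 0),
                       units = c("activity", "suv", "suv_glucose")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive values (mm).")
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L) abort("`origin` must have length 3.")
  structure(
    list(values = values, spacing = spacing, origin = origin, units = units),
    class = "pet_volume"
  )
}

#' @rdname pet_volume
#' @export
tumour_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  vals <- unique(as.vector(values))
  if (!all(vals %in% c(0, 1))) {
    abort("mask values must be strictly 0 or 1.")
  }
  if (sum(values) < 1) {
    abort("mask must contain at least one foreground voxel.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive values (mm).")
  }
  structure(
    list(values = array(as.numeric(values), dim(values)),
         spacing = spacing, origin = as.numeric(origin)),
    class = "tumour_mask"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf(
    "<pet_volume> %s voxels @ %s mm, units: %s, range [%.3g, %.3g]\n",
    paste(dim(x$values), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    x$units, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
print.tumour_mask <- function(x, ...) {
  cat(sprintf(
    "<tumour_mask> %s voxels @ %s mm, %d foreground\n",
    paste(dim(x$values), collapse = "x"),
    paste(format(x$spacing, trim = TRUE), collapse = "x"),
    as.integer(sum(x$values))
  ))
  invisible(x)
}

stopifnot_same_grid <- function(volume, mask) {
  if (!identical(dim(volume$values), dim(mask$values))) {
    abort("volume and mask have different grid dimensions.")
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6) {
    abort("volume and mask have different voxel spacing.")
  }
  invisible(TRUE)
}

#' In-mask voxel values
#'
#' @param volume A [pet_volume()].
#' @param mask A [tumour_mask()] on the same grid.
#' @return Numeric vector of voxel values inside the mask.
#' @export
mask_values <- function(volume, mask) {
  stopifnot_same_grid(volume, mask)
  as.vector(volume$values[mask$values > 0.5])
}

#' Read and write a PET study as NIfTI
#'
#' `read_pet_study()` loads a volume/mask pair from NIfTI-1 files, taking
#' voxel spacing from the headers. Mask voxels are binarised at 0.5 so
#' 0/255-style dialects are tolerated. `write_pet_study()` is its inverse.
#'
#' @param volume_path,mask_path Paths to NIfTI files.
#' @param units Units flag to attach to the volume (files carry no
#'   quantification state).
#' @return A list with elements `volume` ([pet_volume()]) and `mask`
#'   ([tumour_mask()]).
#' @export
read_pet_study <- function(volume_path, mask_path, units = "activity") {
  for (p in c(volume_path, mask_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  vimg <- RNifti::readNifti(volume_path)
  mimg <- RNifti::readNifti(mask_path)
  varr <- array(as.numeric(vimg), dim(vimg))
  marr <- array(as.numeric(mimg), dim(mimg))
  if (!identical(dim(varr), dim(marr))) {
    abort(sprintf("grid mismatch between '%s' (%s) and '%s' (%s)",
                  volume_path, paste(dim(varr), collapse = "x"),
                  mask_path, paste(dim(marr), collapse = "x")))
  }
  vsp <- RNifti::pixdim(vimg)[1:3]
  msp <- RNifti::pixdim(mimg)[1:3]
  if (max(abs(vsp - msp)) > 1e-4) {
    abort(sprintf("spacing mismatch between '%s' and '%s'",
                  volume_path, mask_path))
  }
  marr <- array(as.numeric(marr > 0.5), dim(marr))
  list(
    volume = pet_volume(varr, spacing = vsp, units = units),
    mask = tumour_mask(marr, spacing = vsp)
  )
}

#' @rdname read_pet_study
#' @param volume A [pet_volume()].
#' @param mask A [tumour_mask()] on the same grid.
#' @export
write_pet_study <- function(volume, mask, volume_path, mask_path) {
  stopifnot_same_grid(volume, mask)
  vimg <- RNifti::asNifti(volume$values)
  RNifti::pixdim(vimg) <- volume$spacing
  mimg <- RNifti::asNifti(mask$values)
  RNifti::pixdim(mimg) <- mask$spacing
  RNifti::writeNifti(vimg, volume_path)
  RNifti::writeNifti(mimg, mask_path)
  invisible(c(volume = volume_path, mask = mask_path))
}
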