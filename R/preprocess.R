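#' Convert activity concentration to SUV
#'
#' Body-weight standardised uptake value:
#' `SUV = activity (Bq/mL) * body weight (g) / injected dose (Bq)`.
#' Decay correction is assumed to have been applied to the activity values
#' already, as is standard for reconstructed PET.
#'
#' @param volume A [pet_volume()] with `units == "activity"`.
#' @param meta A list or one-row data frame with `injected_dose_bq` and
#'   `body_weight_kg`.
#' @return A [pet_volume()] with `units == "suv"`.
#' @examples
#' vol <- pet_volume(array(5000, c(2, 2, 2)), spacing = c(2, 2, 2))
#' suv <- to_suv(vol, list(injected_dose_bq = 350e6, body_weight_kg = 70))
#' max(suv$values) # 1.0
#' @export
to_suv <- function(volume, meta) {
  if (volume$units != "activity") {
    abort("`volume` is not in activity units; SUV conversion already applied?")
  }
  dose <- as.numeric(meta$injected_dose_bq)
  weight <- as.numeric(meta$body_weight_kg)
  if (!isTRUE(dose > 0)) abort("injected dose must be strictly positive.")
  if (!isTRUE(weight > 0)) abort("body weight must be strictly positive.")
  out <- volume
  out$values <- volume$values * (weight * 1000) / dose
  out$units <- "suv"
  out
}

#' Correct SUV for serum glucose
#'
#' Normalises SUV to a reference serum glucose level (default 5.0 mmol/L,
#' EANM-style): `SUV' = SUV * glucose / reference`. The correction is
#' linear and commutes with resampling of a constant field.
#'
#' @param volume A [pet_volume()] with `units == "suv"`.
#' @param glucose_mmol_l Serum glucose at injection time (mmol/L).
#' @param reference_mmol_l Reference glucose level (mmol/L).
#' @return A [pet_volume()] with `units == "suv_glucose"`.
#' @export
glucose_correct <- function(volume, glucose_mmol_l, reference_mmol_l = 5.0) {
  if (volume$units != "suv") {
    abort("`volume` must be in SUV units before glucose correction.")
  }
  if (!isTRUE(glucose_mmol_l > 0)) abort("glucose must be strictly positive.")
  if (!isTRUE(reference_mmol_l > 0)) abort("reference glucose must be positive.")
  out <- volume
  out$values <- volume$values * glucose_mmol_l / reference_mmol_l
  out$units <- "suv_glucose"
  out
}

# Vectorized trilinear interpolation of a 3D array at continuous 0-based
# voxel coordinates (n x 3 matrix). Coordinates are clamped to the grid
# (nearest extension beyond the border).
interp_trilinear <- function(values, coords) {
  d <- dim(values)
  cl <- function(x, n) pmin(pmax(x, 0), n - 1)
  x <- cl(coords[, 1], d[1]); y <- cl(coords[, 2], d[2]); z <- cl(coords[, 3], d[3])
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v <- as.vector(values)
  c000 <- v[idx(x0, y0, z0)]; c100 <- v[idx(x1, y0, z0)]
  c010 <- v[idx(x0, y1, z0)]; c110 <- v[idx(x1, y1, z0)]
  c001 <- v[idx(x0, y0, z1)]; c101 <- v[idx(x1, y0, z1)]
  c011 <- v[idx(x0, y1, z1)]; c111 <- v[idx(x1, y1, z1)]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

# Output grid for a target spacing: keeps the physical extent within one
# voxel and samples at origin + j * target (0-based).
target_grid_dims <- function(in_dim, in_spacing, target) {
  extent <- (in_dim - 1) * in_spacing
  pmax(floor(extent / target + 1e-9) + 1L, 1L)
}

#' Resample a PET volume to an isotropic grid
#'
#' Trilinear interpolation onto a uniform grid (default 2 x 2 x 2 mm),
#' preserving the physical extent within one voxel. Texture analysis
#' requires a uniform isotropic lattice so that co-occurrence offsets have
#' equal physical length in all directions.
#'
#' @param volume A [pet_volume()].
#' @param target_mm Target spacing in mm (length 1 or 3).
#' @return A resampled [pet_volume()] with `spacing == target_mm`.
#' @export
resample_isotropic <- function(volume, target_mm = c(2, 2, 2)) {
  target <- rep(as.numeric(target_mm), length.out = 3)
  if (any(target <= 0)) abort("target spacing must be strictly positive.")
  d <- dim(volume$values)
  if (any(d < 2)) {
    abort("cannot resample a degenerate (single-slice) volume.")
  }
  nd <- target_grid_dims(d, volume$spacing, target)
  # continuous input-voxel coordinate of each output voxel centre
  g <- expand.grid(
    x = (seq_len(nd[1]) - 1) * target[1] / volume$spacing[1],
    y = (seq_len(nd[2]) - 1) * target[2] / volume$spacing[2],
    z = (seq_len(nd[3]) - 1) * target[3] / volume$spacing[3]
  )
  vals <- interp_trilinear(volume$values, as.matrix(g))
  pet_volume(array(vals, nd), spacing = target, origin = volume$origin,
             units = volume$units)
}

#' Resample a tumour mask onto a target grid
#'
#' Nearest-neighbour resampling keeps the mask strictly binary. Errors if
#' the ROI is lost entirely (for example by resampling far off-grid).
#'
#' @param mask A [tumour_mask()].
#' @param target_grid A [pet_volume()] defining the output lattice, or a
#'   numeric target spacing in mm.
#' @return A binary [tumour_mask()] on the target grid.
#' @export
resample_mask <- function(mask, target_grid) {
  if (inherits(target_grid, "pet_volume")) {
    nd <- dim(target_grid$values)
    target <- target_grid$spacing
  } else {
    target <- rep(as.numeric(target_grid), length.out = 3)
    nd <- target_grid_dims(dim(mask$values), mask$spacing, target)
  }
  d <- dim(mask$values)
  gx <- round((seq_len(nd[1]) - 1) * target[1] / mask$spacing[1])
  gy <- round((seq_len(nd[2]) - 1) * target[2] / mask$spacing[2])
  gz <- round((seq_len(nd[3]) - 1) * target[3] / mask$spacing[3])
  gx <- pmin(pmax(gx, 0), d[1] - 1) + 1
  gy <- pmin(pmax(gy, 0), d[2] - 1) + 1
  gz <- pmin(pmax(gz, 0), d[3] - 1) + 1
  out <- mask$values[gx, gy, gz, drop = FALSE]
  out <- array(out, nd)
  if (sum(out) < 1) abort("ROI lost during mask resampling (empty output).")
  tumour_mask(out, spacing = target, origin = mask$origin)
}

#' Discretise ROI intensities into grey levels
#'
#' Two IBSI discretisation schemes. Fixed bin number maps the in-mask
#' intensity range onto `Ng` levels:
#' `level = min(Ng, floor(Ng * (x - min) / (max - min)) + 1)`.
#' Fixed bin size uses `level = floor((x - min) / w) + 1` with bin width
#' `w` in intensity units. A constant ROI under fixed bin number yields a
#' single level (level 1), which downstream features treat as the
#' degenerate homogeneous case, not an error.
#'
#' @param volume A preprocessed [pet_volume()].
#' @param mask A [tumour_mask()] on the same grid.
#' @param scheme `"fixed_bin_number"` or `"fixed_bin_size"`.
#' @param bin_param Number of grey levels `Ng >= 2` (fixed bin number) or
#'   bin width in intensity units (fixed bin size).
#' @return An object of class `discretised_roi`: a list with `levels`
#'   (integer array, `NA` outside the mask), `n_levels`, `scheme`,
#'   `bin_param`, and the grid `spacing`.
#' @export
discretise <- function(volume, mask,
                       scheme = c("fixed_bin_number", "fixed_bin_size"),
                       bin_param = 64) {
  scheme <- match.arg(scheme)
  stopifnot_same_grid(volume, mask)
  inside <- mask$values > 0.5
  x <- volume$values[inside]
  if (length(x) == 0) abort("empty ROI.")
  lev <- array(NA_integer_, dim(volume$values))
  if (scheme == "fixed_bin_number") {
    ng <- as.integer(bin_param)
    if (ng < 2) abort("fixed_bin_number requires Ng >= 2.")
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) {
      lev[inside] <- 1L
      ng_eff <- 1L
    } else {
      l <- pmin(ng, floor(ng * (x - rng[1]) / (rng[2] - rng[1])) + 1)
      lev[inside] <- as.integer(l)
      ng_eff <- ng
    }
  } else {
    w <- as.numeric(bin_param)
    if (!isTRUE(w > 0)) abort("fixed_bin_size requires a positive bin width.")
    l <- floor((x - min(x)) / w) + 1
    lev[inside] <- as.integer(l)
    ng_eff <- as.integer(max(l))
  }
  structure(
    list(levels = lev, n_levels = ng_eff, scheme = scheme,
         bin_param = bin_param, spacing = volume$spacing),
    class = "discretised_roi"
  )
}

#' @export
print.discretised_roi <- function(x, ...) {
  cat(sprintf("<discretised_roi> %d in-mask voxels, %d grey levels (%s)\n",
              sum(!is.na(x$levels)), x$n_levels, x$scheme))
  invisible(x)
}

# Separable Gaussian blur of a 3D array, sigma in voxels per axis.
# Kernel rows renormalised at the borders (no intensity leak).
blur3d <- function(arr, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-8) next
    n <- d[ax]
    idx <- seq_len(n)
    K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * s^2)))
    K <- K / rowSums(K)
    perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    a <- aperm(arr, perm)
    dd <- dim(a)
    m <- K %*% matrix(a, nrow = dd[1])
    a <- array(m, dd)
    arr <- aperm(a, order(perm))
  }
  arr
}
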