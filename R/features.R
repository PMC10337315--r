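#' First-order intensity statistics
#'
#' The IBSI intensity-statistics family on in-mask voxel values. Note the
#' IBSI "median absolute deviation" is the *mean* absolute deviation from
#' the median, `(1/N) * sum |x_i - median(x)|`; the robust variant uses
#' only voxels inside the 10th-90th percentile band. Kurtosis is excess
#' kurtosis. Degenerate (constant) ROIs return 0 for the shape moments.
#'
#' @param volume A [pet_volume()].
#' @param mask A [tumour_mask()] on the same grid.
#' @return Named numeric vector of intensity statistics.
#' @examples
#' vol <- pet_volume(array(c(1, 2, 3, 6), c(2, 2, 1)), c(2, 2, 2))
#' msk <- tumour_mask(array(1, c(2, 2, 1)), c(2, 2, 2))
#' intensity_stats(vol, msk)[["median_absolute_deviation"]] # 1.5
#' @export
intensity_stats <- function(volume, mask) {
  x <- mask_values(volume, mask)
  if (length(x) == 0) abort("empty ROI.")
  m <- mean(x)
  v <- mean((x - m)^2) # population variance, IBSI convention
  s <- sqrt(v)
  med <- median(x)
  q <- quantile(x, c(.1, .25, .75, .9), names = FALSE, type = 7)
  skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - m)^4) / s^4 - 3 else 0
  band <- x[x >= q[1] & x <= q[4]]
  c(
    mean = m,
    variance = v,
    sd = s,
    skewness = skew,
    kurtosis = kurt,
    median = med,
    minimum = min(x),
    p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4],
    maximum = max(x),
    interquartile_range = q[3] - q[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - m)),
    robust_mean_absolute_deviation = mean(abs(band - mean(band))),
    median_absolute_deviation = mean(abs(x - med)),
    coefficient_of_variation = if (m != 0) s / m else 0,
    quartile_coefficient_dispersion =
      if ((q[3] + q[2]) != 0) (q[3] - q[2]) / (q[3] + q[2]) else 0,
    energy = sum(x^2),
    root_mean_square = sqrt(mean(x^2))
  )
}

#' Intensity-histogram features
#'
#' Histogram-domain statistics on discretised grey levels. Entropy is in
#' bits; uniformity is the sum of squared level probabilities.
#'
#' @param droi A [discretise()]d ROI.
#' @return Named numeric vector of histogram features.
#' @export
histogram_features <- function(droi) {
  lv <- droi$levels[!is.na(droi$levels)]
  if (length(lv) == 0) abort("empty ROI.")
  ng <- max(droi$n_levels, max(lv))
  pr <- tabulate(lv, nbins = ng) / length(lv)
  m <- sum(seq_len(ng) * pr)
  v <- sum((seq_len(ng) - m)^2 * pr)
  s <- sqrt(v)
  med <- median(lv)
  lp <- pr[pr > 0]
  c(
    mean = m,
    variance = v,
    skewness = if (s > 0) sum((seq_len(ng) - m)^3 * pr) / s^3 else 0,
    kurtosis = if (s > 0) sum((seq_len(ng) - m)^4 * pr) / s^4 - 3 else 0,
    median = med,
    minimum = min(lv),
    p10 = quantile(lv, .1, names = FALSE),
    p90 = quantile(lv, .9, names = FALSE),
    maximum = max(lv),
    mode = which.max(pr),
    interquartile_range = quantile(lv, .75, names = FALSE) -
      quantile(lv, .25, names = FALSE),
    range = max(lv) - min(lv),
    mean_absolute_deviation = mean(abs(lv - mean(lv))),
    median_absolute_deviation = mean(abs(lv - med)),
    coefficient_of_variation = if (m != 0) s / m else 0,
    entropy = -sum(lp * log2(lp)),
    uniformity = sum(pr^2)
  )
}

#' Morphological features
#'
#' Voxel-based morphology of the ROI: volume, surface area from exposed
#' voxel faces (a voxel-face approximation of the IBSI mesh surface),
#' sphericity, maximum 3D diameter over surface voxels, and principal-axis
#' measures from the voxel-coordinate covariance.
#'
#' @param mask A [tumour_mask()]; spacing should be isotropic after
#'   preprocessing but anisotropic grids are handled.
#' @return Named numeric vector of morphology features.
#' @export
morphology_features <- function(mask) {
  sp <- mask$spacing
  m <- mask$values > 0.5
  n <- sum(m)
  vox_vol <- prod(sp)
  volume_mm3 <- n * vox_vol

  # exposed-face surface area
  d <- dim(m)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  shift_ax <- function(a, ax, by) {
    idx <- lapply(dim(a), seq_len)
    idx[[ax]] <- idx[[ax]] + by
    idx[[ax]] <- pmin(pmax(idx[[ax]], 1), dim(a)[ax])
    do.call(`[`, c(list(a), idx))
  }
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- 0
  surface <- array(FALSE, dim(pad))
  for (ax in 1:3) {
    for (by in c(-1, 1)) {
      exposed <- pad & !shift_ax(pad, ax, by)
      area <- area + sum(exposed) * face_area[ax]
      surface <- surface | exposed
    }
  }

  coords <- which(pad, arr.ind = TRUE)
  wc <- sweep(coords, 2, sp, `*`)
  surf_wc <- sweep(which(surface, arr.ind = TRUE), 2, sp, `*`)
  max_diam <- if (nrow(surf_wc) > 1) {
    if (nrow(surf_wc) > 2500) { # deterministic thinning for very large ROIs
      surf_wc <- surf_wc[seq(1, nrow(surf_wc), length.out = 2500), , drop = FALSE]
    }
    sqrt(max(as.matrix(stats::dist(surf_wc))^2))
  } else 0

  if (n > 1) {
    ev <- sort(eigen(stats::cov(wc), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  sphericity <- if (area > 0) (pi^(1 / 3) * (6 * volume_mm3)^(2 / 3)) / area else 0

  c(
    volume_ml = volume_mm3 / 1000,
    voxel_count = n,
    surface_area_mm2 = area,
    surface_to_volume_ratio = if (volume_mm3 > 0) area / volume_mm3 else 0,
    sphericity = sphericity,
    compactness = if (area > 0) 36 * pi * volume_mm3^2 / area^3 else 0,
    max_diameter_mm = max_diam,
    major_axis_mm = axes[1],
    minor_axis_mm = axes[2],
    least_axis_mm = axes[3],
    elongation = if (axes[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    flatness = if (axes[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}

# --- grey-level run length -------------------------------------------------

# All maximal runs of equal level along one direction; vectorized over
# lines by sorting on (line key, position along direction).
runs_for_direction <- function(droi, dir) {
  lev <- droi$levels
  idx <- which(!is.na(lev), arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  l <- lev[cbind(idx[, 1], idx[, 2], idx[, 3])]
  p <- idx[, 1] * dir[1] + idx[, 2] * dir[2] + idx[, 3] * dir[3]
  dd <- sum(dir * dir)
  k1 <- idx[, 1] * dd - p * dir[1]
  k2 <- idx[, 2] * dd - p * dir[2]
  k3 <- idx[, 3] * dd - p * dir[3]
  B <- 4096; C <- 2048
  key <- ((k1 + C) * B + (k2 + C)) * B + (k3 + C)
  o <- order(key, p)
  key <- key[o]; p <- p[o]; l <- l[o]
  newrun <- c(TRUE, diff(key) != 0 | diff(p) != dd | diff(l) != 0)
  runid <- cumsum(newrun)
  list(level = l[newrun], length = tabulate(runid))
}

#' Grey-level run-length features
#'
#' IBSI GLRLM family: run-length matrices are formed along each of the 13
#' unique 3D directions and features are averaged over directions.
#'
#' @param droi A [discretise()]d ROI.
#' @return Named numeric vector of GLRLM features.
#' @export
glrlm_features <- function(droi) {
  nv <- sum(!is.na(droi$levels))
  dirs <- glcm_directions()
  feats <- NULL
  nd <- 0
  for (k in seq_len(nrow(dirs))) {
    runs <- runs_for_direction(droi, dirs[k, ])
    if (is.null(runs) || length(runs$level) == 0) next
    f <- rl_matrix_features(runs$level, runs$length, nv,
                            prefix_short = "short_run", prefix_long = "long_run",
                            size_name = "run_length", pct_name = "run_percentage",
                            entropy_name = "run_entropy")
    feats <- if (is.null(feats)) f else feats + f
    nd <- nd + 1
  }
  if (nd == 0) abort("no runs: empty ROI.")
  feats / nd
}

# Shared size-distribution features for run-length and size-zone families:
# counts n_k of elements with grey level g_k and size s_k.
rl_matrix_features <- function(glev, gsize, nv,
                               prefix_short, prefix_long,
                               size_name, pct_name, entropy_name) {
  ns <- length(glev)
  i <- as.numeric(glev); s <- as.numeric(gsize)
  pr <- rep(1 / ns, ns)
  gl_tab <- tapply(rep(1, ns), glev, sum)
  sz_tab <- tapply(rep(1, ns), gsize, sum)
  mu_g <- sum(i * pr); mu_s <- sum(s * pr)
  out <- c(
    sum(1 / s^2) / ns,                # short emphasis
    sum(s^2) / ns,                    # long emphasis
    sum(1 / i^2) / ns,                # low grey level
    sum(i^2) / ns,                    # high grey level
    sum(1 / (i^2 * s^2)) / ns,
    sum(i^2 / s^2) / ns,
    sum(s^2 / i^2) / ns,
    sum(i^2 * s^2) / ns,
    sum(gl_tab^2) / ns,               # grey-level non-uniformity
    sum(gl_tab^2) / ns^2,
    sum(sz_tab^2) / ns,               # size non-uniformity
    sum(sz_tab^2) / ns^2,
    ns / nv,                          # percentage
    sum((i - mu_g)^2 * pr),           # grey-level variance
    sum((s - mu_s)^2 * pr),           # size variance
    -sum(pr * log2(pr))               # entropy of (level, size) cells?
  )
  # entropy over distinct (level, size) cells, matching matrix-form entropy
  cell <- paste(glev, gsize)
  pc <- as.numeric(table(cell)) / ns
  out[16] <- -sum(pc * log2(pc))
  names(out) <- c(
    paste0(prefix_short, "_emphasis"),
    paste0(prefix_long, "_emphasis"),
    "low_grey_level_emphasis",
    "high_grey_level_emphasis",
    paste0(prefix_short, "_low_grey_level_emphasis"),
    paste0(prefix_short, "_high_grey_level_emphasis"),
    paste0(prefix_long, "_low_grey_level_emphasis"),
    paste0(prefix_long, "_high_grey_level_emphasis"),
    "grey_level_non_uniformity",
    "grey_level_non_uniformity_norm",
    paste0(size_name, "_non_uniformity"),
    paste0(size_name, "_non_uniformity_norm"),
    pct_name,
    "grey_level_variance",
    paste0(size_name, "_variance"),
    entropy_name
  )
  out
}

# --- grey-level size zone --------------------------------------------------

# 26-connected zones of equal grey level; frontier-based flood fill,
# vectorized over the frontier at each step.
glszm_zones <- function(droi) {
  lev <- droi$levels
  d <- dim(lev)
  lab <- array(0L, d)
  nb <- glcm_directions()
  nb <- rbind(nb, -nb) # all 26 neighbours
  zone_level <- integer(0)
  zone_size <- integer(0)
  todo <- which(!is.na(lev) & lab == 0L)
  while (length(todo) > 0) {
    seed <- todo[1]
    zid <- length(zone_level) + 1L
    target <- lev[seed]
    lab[seed] <- zid
    frontier <- seed
    size <- 1L
    while (length(frontier) > 0) {
      ai <- arrayInd(frontier, d)
      cand <- NULL
      for (k in seq_len(nrow(nb))) {
        ni <- sweep(ai, 2, nb[k, ], `+`)
        ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] &
          ni[, 2] >= 1 & ni[, 2] <= d[2] &
          ni[, 3] >= 1 & ni[, 3] <= d[3]
        if (!any(ok)) next
        lin <- ni[ok, 1] + d[1] * (ni[ok, 2] - 1) + d[1] * d[2] * (ni[ok, 3] - 1)
        lin <- lin[!is.na(lev[lin]) & lev[lin] == target & lab[lin] == 0L]
        cand <- c(cand, lin)
      }
      cand <- unique(cand)
      if (length(cand) > 0) lab[cand] <- zid
      size <- size + length(cand)
      frontier <- cand
    }
    zone_level[zid] <- target
    zone_size[zid] <- size
    todo <- which(!is.na(lev) & lab == 0L)
  }
  list(level = zone_level, size = zone_size)
}

#' Grey-level size-zone features
#'
#' IBSI GLSZM family: zones are 26-connected components of equal grey
#' level; a single matrix is formed (no directionality).
#'
#' @param droi A [discretise()]d ROI.
#' @return Named numeric vector of GLSZM features.
#' @export
glszm_features <- function(droi) {
  nv <- sum(!is.na(droi$levels))
  if (nv == 0) abort("empty ROI.")
  z <- glszm_zones(droi)
  rl_matrix_features(z$level, z$size, nv,
                     prefix_short = "small_zone", prefix_long = "large_zone",
                     size_name = "zone_size", pct_name = "zone_percentage",
                     entropy_name = "zone_entropy")
}

#' Feature-extraction configuration
#'
#' @param discretisation List with `scheme` and `bin_param`; see
#'   [discretise()]. Default: fixed bin number with 64 levels, a common
#'   IBSI choice (the development study's setting is not published in a
#'   recoverable form, so this is configurable).
#' @param glcm_distance Chebyshev co-occurrence distance in voxels.
#' @param glcm_aggregation `"average"` or `"merge"`, see [compute_glcm()].
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(discretisation = list(scheme = "fixed_bin_number",
                                                 bin_param = 64),
                           glcm_distance = 1,
                           glcm_aggregation = "average") {
  structure(
    list(discretisation = discretisation, glcm_distance = glcm_distance,
         glcm_aggregation = glcm_aggregation),
    class = "feature_config"
  )
}

#' Extract the full radiomic feature vector
#'
#' Computes the fixed, documented feature set over the morphology,
#' intensity-statistics, intensity-histogram, GLCM, GLRLM and GLSZM
#' families on a preprocessed volume/mask pair. Column names are prefixed
#' by family (`morph_`, `stat_`, `hist_`, `glcm_`, `glrlm_`, `glszm_`);
#' extraction is deterministic given inputs and config, and the config
#' hash is recorded for provenance.
#'
#' @param volume A preprocessed [pet_volume()] (SUV or glucose-corrected
#'   SUV on the isotropic grid).
#' @param mask A [tumour_mask()] on the same grid.
#' @param config A [feature_config()].
#' @return One-row tibble of features plus a `config_hash` column.
#' @export
extract_features <- function(volume, mask, config = feature_config()) {
  stopifnot_same_grid(volume, mask)
  if (sum(mask$values) < 1) abort("empty mask.")
  droi <- discretise(volume, mask,
                     scheme = config$discretisation$scheme,
                     bin_param = config$discretisation$bin_param)
  glcm <- compute_glcm(droi, distance = config$glcm_distance,
                       aggregation = config$glcm_aggregation)
  prefixed <- function(f, prefix) setNames(f, paste0(prefix, names(f)))
  feats <- c(
    prefixed(morphology_features(mask), "morph_"),
    prefixed(intensity_stats(volume, mask), "stat_"),
    prefixed(histogram_features(droi), "hist_"),
    prefixed(glcm_features(glcm), "glcm_"),
    prefixed(glrlm_features(droi), "glrlm_"),
    prefixed(glszm_features(droi), "glszm_")
  )
  out <- as_tibble(as.list(feats))
  out$config_hash <- config_hash(paste(
    config$discretisation$scheme, config$discretisation$bin_param,
    config$glcm_distance, config$glcm_aggregation
  ))
  out
}

#' Names of feature columns in a feature table
#'
#' @param table A feature table (tibble).
#' @return Character vector of radiomic feature column names (those with
#'   a family prefix).
#' @export
feature_columns <- function(table) {
  grep("^(morph|stat|hist|glcm|glrlm|glszm)_", names(table), value = TRUE)
}
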