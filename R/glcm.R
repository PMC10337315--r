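#' Grey-level co-occurrence matrix
#'
#' Counts co-occurrences of grey levels over the 13 unique 3D direction
#' offsets at a given Chebyshev distance, symmetrises (each voxel pair is
#' counted in both orders), and normalises to a joint probability matrix
#' `p(i, j)`. With `aggregation = "average"` a probability matrix is
#' formed per direction (directions without any voxel pair are skipped)
#' and the matrices are averaged; with `"merge"` counts are pooled across
#' directions before normalising.
#'
#' @param droi A [discretise()]d ROI.
#' @param distance Chebyshev offset distance in voxels.
#' @param aggregation `"average"` (average over per-direction matrices,
#'   the default) or `"merge"` (pool counts).
#' @return An object of class `glc_matrix`: list with the `Ng x Ng`
#'   probability matrix `p`, `n_levels`, `distance` and `aggregation`.
#' @examples
#' vol <- pet_volume(array(c(1, 2), c(1, 1, 2)), spacing = c(2, 2, 2),
#'                   units = "suv_glucose")
#' msk <- tumour_mask(array(1, c(1, 1, 2)), spacing = c(2, 2, 2))
#' g <- compute_glcm(discretise(vol, msk, bin_param = 2))
#' g$p # 0 / 0.5 off-diagonal
#' @export
compute_glcm <- function(droi, distance = 1,
                         aggregation = c("average", "merge")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(droi, "discretised_roi"))
  if (!isTRUE(distance >= 1)) abort("`distance` must be >= 1 voxel.")
  ng <- max(droi$n_levels, 1L)
  lev <- droi$levels
  dirs <- glcm_directions() * as.integer(distance)
  mats <- list()
  merged <- matrix(0, ng, ng)
  n_pairs_total <- 0
  for (k in seq_len(nrow(dirs))) {
    cnt <- offset_pair_counts(lev, dirs[k, ], ng)
    npair <- sum(cnt)
    if (npair == 0) next
    n_pairs_total <- n_pairs_total + npair
    sym <- cnt + t(cnt)
    if (aggregation == "average") {
      mats[[length(mats) + 1]] <- sym / sum(sym)
    } else {
      merged <- merged + sym
    }
  }
  if (n_pairs_total == 0) {
    abort("no co-occurrences: ROI too small for the requested offset.")
  }
  p <- if (aggregation == "average") {
    Reduce(`+`, mats) / length(mats)
  } else {
    merged / sum(merged)
  }
  structure(
    list(p = p, n_levels = ng, distance = distance, aggregation = aggregation,
         symmetric = TRUE),
    class = "glc_matrix"
  )
}

# The 13 unique 3D offsets (one per direction up to sign).
glcm_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 |
    (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# Directed pair counts for one offset over a level array with NA outside
# the ROI; vectorized subarray alignment.
offset_pair_counts <- function(lev, off, ng) {
  d <- dim(lev)
  rng <- function(n, o) {
    if (o >= 0) list(src = seq_len(n - o), dst = seq_len(n - o) + o)
    else list(src = seq_len(n + o) - o, dst = seq_len(n + o))
  }
  if (any(abs(off) >= d)) return(matrix(0, ng, ng))
  rx <- rng(d[1], off[1]); ry <- rng(d[2], off[2]); rz <- rng(d[3], off[3])
  a <- lev[rx$src, ry$src, rz$src, drop = FALSE]
  b <- lev[rx$dst, ry$dst, rz$dst, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  ai <- a[ok]; bi <- b[ok]
  matrix(tabulate((ai - 1L) * ng + bi, nbins = ng * ng), ng, ng, byrow = TRUE)
}

#' GLCM texture features
#'
#' The IBSI co-occurrence feature family computed from a normalised,
#' symmetric GLCM. All entropies use log base 2 (bits) with the
#' `0 * log 0 = 0` convention. For a single-level (homogeneous) ROI the
#' correlation-type features take their homogeneous-limit conventions
#' (correlation 1, information correlations 0).
#'
#' @param glcm A [compute_glcm()] result.
#' @return Named numeric vector of GLCM features.
#' @export
glcm_features <- function(glcm) {
  p <- glcm$p
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  log2p <- function(q) ifelse(q > 0, log2(q), 0)

  # diagonal and cross-diagonal marginals
  diff_k <- 0:(ng - 1)
  p_diff <- vapply(diff_k, function(k) sum(p[abs(i - j) == k]), numeric(1))
  sum_k <- 2:(2 * ng)
  p_sum <- vapply(sum_k, function(k) sum(p[(i + j) == k]), numeric(1))

  da <- sum(diff_k * p_diff)
  sa <- sum(sum_k * p_sum)

  hxy <- -sum(p * log2p(p))
  hx <- -sum(px * log2p(px))
  pxy <- outer(px, px)
  hxy1 <- -sum(p * log2p(pxy))
  hxy2 <- -sum(pxy * log2p(pxy))

  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- max(0, 1 - exp(-2 * (hxy2 - hxy)))

  offdiag <- i != j
  c(
    joint_maximum = max(p),
    joint_average = mu,
    joint_variance = sig2,
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum((diff_k - da)^2 * p_diff),
    difference_entropy = -sum(p_diff * log2p(p_diff)),
    sum_average = sa,
    sum_variance = sum((sum_k - sa)^2 * p_sum),
    sum_entropy = -sum(p_sum * log2p(p_sum)),
    angular_second_moment = sum(p^2),
    contrast = sum((i - j)^2 * p),
    dissimilarity = sum(abs(i - j) * p),
    inverse_difference = sum(p / (1 + abs(i - j))),
    inverse_difference_norm = sum(p / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    inverse_difference_moment_norm = sum(p / (1 + (i - j)^2 / ng^2)),
    inverse_variance = sum(p[offdiag] / (i[offdiag] - j[offdiag])^2),
    correlation = corr,
    autocorrelation = sum(i * j * p),
    cluster_tendency = sum((i + j - 2 * mu)^2 * p),
    cluster_shade = sum((i + j - 2 * mu)^3 * p),
    cluster_prominence = sum((i + j - 2 * mu)^4 * p),
    information_correlation_1 = ic1,
    information_correlation_2 = sqrt(ic2)
  )
}
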