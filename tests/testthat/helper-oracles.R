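# Independent brute-force oracles. Everything here is deliberately naive
# (explicit loops, full enumeration) and shares no code with the package
# implementations it checks.

# Directed co-occurrence counting by looping over every voxel and offset.
oracle_glcm <- function(levels, ng, distance = 1, aggregation = "average") {
  d <- dim(levels)
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  ) * distance
  mats <- list()
  merged <- matrix(0, ng, ng)
  for (k in seq_len(nrow(dirs))) {
    cnt <- matrix(0, ng, ng)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      a <- levels[x, y, z]
      if (is.na(a)) next
      for (sgn in c(1, -1)) {
        xx <- x + sgn * dirs[k, 1]; yy <- y + sgn * dirs[k, 2]
        zz <- z + sgn * dirs[k, 3]
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
            zz < 1 || zz > d[3]) next
        b <- levels[xx, yy, zz]
        if (is.na(b)) next
        cnt[a, b] <- cnt[a, b] + 1
      }
    }
    if (sum(cnt) == 0) next
    if (aggregation == "average") {
      mats[[length(mats) + 1]] <- cnt / sum(cnt)
    } else {
      merged <- merged + cnt
    }
  }
  if (aggregation == "average") Reduce(`+`, mats) / length(mats)
  else merged / sum(merged)
}

# Direct-summation GLCM features with scalar loops.
oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  jmax <- -Inf; jent <- 0; asm <- 0; iv <- 0; contrast <- 0; dissim <- 0
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) {
    mu <- mu + i * p[i, j]
    if (p[i, j] > jmax) jmax <- p[i, j]
    if (p[i, j] > 0) jent <- jent - p[i, j] * log2(p[i, j])
    asm <- asm + p[i, j]^2
    if (i != j) iv <- iv + p[i, j] / (i - j)^2
    contrast <- contrast + (i - j)^2 * p[i, j]
    dissim <- dissim + abs(i - j) * p[i, j]
  }
  sig2 <- 0
  for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  psum <- rep(0, 2 * ng)
  pdiff <- rep(0, ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  sent <- 0
  for (k in 2:(2 * ng)) if (psum[k] > 0) sent <- sent - psum[k] * log2(psum[k])
  dent <- 0
  for (k in 1:ng) if (pdiff[k] > 0) dent <- dent - pdiff[k] * log2(pdiff[k])
  corr <- if (sig2 > 0) {
    acc <- 0
    for (i in 1:ng) for (j in 1:ng) acc <- acc + i * j * p[i, j]
    (acc - mu^2) / sig2
  } else 1
  list(joint_maximum = jmax, joint_entropy = jent, sum_entropy = sent,
       difference_entropy = dent, angular_second_moment = asm,
       inverse_variance = iv, contrast = contrast, dissimilarity = dissim,
       joint_average = mu, joint_variance = sig2, correlation = corr)
}

# Intensity statistics from their definitions.
oracle_intensity_stats <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / n
  med <- median(x)
  list(mean = m, variance = v,
       skewness = if (v > 0) (sum((x - m)^3) / n) / v^1.5 else 0,
       kurtosis = if (v > 0) (sum((x - m)^4) / n) / v^2 - 3 else 0,
       median_absolute_deviation = sum(abs(x - med)) / n,
       mean_absolute_deviation = sum(abs(x - m)) / n,
       energy = sum(x^2), root_mean_square = sqrt(sum(x^2) / n))
}

# Histogram features from an explicit tabulation.
oracle_histogram <- function(lv, ng) {
  cnt <- rep(0, ng)
  for (l in lv) cnt[l] <- cnt[l] + 1
  pr <- cnt / length(lv)
  ent <- 0
  for (q in pr) if (q > 0) ent <- ent - q * log2(q)
  list(entropy = ent, uniformity = sum(pr^2),
       mean = sum(seq_len(ng) * pr), mode = which.max(pr))
}

# Maximal runs along one direction by walking each voxel.
oracle_runs <- function(levels, dir) {
  d <- dim(levels)
  inb <- function(v) all(v >= 1) && all(v <= d)
  runs_level <- integer(0); runs_len <- integer(0)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    v <- c(x, y, z)
    if (is.na(levels[x, y, z])) next
    prev <- v - dir
    if (inb(prev) && !is.na(levels[prev[1], prev[2], prev[3]]) &&
        levels[prev[1], prev[2], prev[3]] == levels[x, y, z]) next
    len <- 1
    nxt <- v + dir
    while (inb(nxt) && !is.na(levels[nxt[1], nxt[2], nxt[3]]) &&
           levels[nxt[1], nxt[2], nxt[3]] == levels[x, y, z]) {
      len <- len + 1
      nxt <- nxt + dir
    }
    runs_level <- c(runs_level, levels[x, y, z])
    runs_len <- c(runs_len, len)
  }
  list(level = runs_level, length = runs_len)
}

# 26-connected zone labelling by iterated label propagation.
oracle_zones <- function(levels) {
  d <- dim(levels)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(!is.na(levels), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    nxt <- nxt + 1L
    lab[idx[r, 1], idx[r, 2], idx[r, 3]] <- nxt
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(idx))) {
      x <- idx[r, 1]; y <- idx[r, 2]; z <- idx[r, 3]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        xx <- x + dx; yy <- y + dy; zz <- z + dz
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
            zz < 1 || zz > d[3]) next
        if (is.na(levels[xx, yy, zz])) next
        if (levels[xx, yy, zz] != levels[x, y, z]) next
        if (lab[xx, yy, zz] < lab[x, y, z]) {
          lab[x, y, z] <- lab[xx, yy, zz]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  zl <- integer(0); zs <- integer(0)
  for (u in unique(lab[lab > 0])) {
    sel <- which(lab == u)
    zl <- c(zl, levels[sel[1]])
    zs <- c(zs, length(sel))
  }
  list(level = zl, size = zs)
}

# AUC by explicit pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  acc <- 0
  for (a in pos) for (b in neg) {
    acc <- acc + (a > b) + 0.5 * (a == b)
  }
  acc / (length(pos) * length(neg))
}

# Maximum-likelihood logistic fit of y ~ a + b * x by Newton iteration,
# and offset-form intercept (slope fixed at 1) by scalar Newton.
oracle_logistic_mle <- function(x, y, tol = 1e-12) {
  beta <- c(0, 0)
  X <- cbind(1, x)
  for (it in 1:200) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    score <- t(X) %*% (y - p)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  a <- 0
  for (it in 1:200) {
    p <- 1 / (1 + exp(-(a + x)))
    g <- sum(y - p)
    h <- sum(p * (1 - p))
    step <- g / h
    a <- a + step
    if (abs(step) < tol) break
  }
  list(intercept = beta[1], slope = beta[2], offset_intercept = a)
}

# Two-sided Fisher exact p by full hypergeometric enumeration.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) dhyper(a, c1, n - c1, r1), numeric(1))
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating group assignments.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(xi, yi) {
    acc <- 0
    for (a in xi) for (b in yi) acc <- acc + (a > b) + 0.5 * (a == b)
    acc
  }
  u_obs <- u_of(x, y)
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}
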