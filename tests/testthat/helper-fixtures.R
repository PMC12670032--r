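# Shared fixtures and independent brute-force oracles.

# A small, fast phantom specification for unit tests (the full-size default
# spec is exercised in the acceptance tests).
tiny_spec <- function(...) {
  phantom_spec(shape = c(32, 32, 12), radius_range_mm = c(6, 7.5), ...)
}

# Constant-intensity stack over an ellipsoidal region.
constant_stack <- function(dim = c(32, 32, 12), spacing = c(1, 1, 3),
                           value = 0) {
  vols <- setNames(lapply(1:4, function(i) array(value, dim)),
                   c("T2", "PRE", "AP", "HBP"))
  volume_stack("const", vols, spacing)
}

ellipsoid_region <- function(dim = c(32, 32, 12), spacing = c(1, 1, 3),
                             center = dim * spacing / 2, semi = c(10, 10, 12)) {
  x <- (seq_len(dim[1]) - 1) * spacing[1]
  y <- (seq_len(dim[2]) - 1) * spacing[2]
  z <- (seq_len(dim[3]) - 1) * spacing[3]
  q <- outer(outer(((x - center[1]) / semi[1])^2,
                   ((y - center[2]) / semi[2])^2, "+"),
             ((z - center[3]) / semi[3])^2, "+")
  q <= 1
}

# Brute-force anisotropic distance map: for every voxel, the minimum
# Euclidean distance (mm) to any foreground voxel centre. O(n * m), for
# small instances only.
bf_distance_map <- function(mask, spacing) {
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  fgmm <- sweep(fg - 1, 2, spacing, "*")
  out <- array(Inf, d)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  allmm <- sweep(all_idx - 1, 2, spacing, "*")
  for (k in seq_len(nrow(fgmm))) {
    dd <- sqrt((allmm[, 1] - fgmm[k, 1])^2 + (allmm[, 2] - fgmm[k, 2])^2 +
                 (allmm[, 3] - fgmm[k, 3])^2)
    out <- pmin(out, array(dd, d))
  }
  out
}

# Brute-force GLCM counts (symmetric, 13 directions) by explicit loops.
bf_glcm <- function(lev, ng) {
  d <- dim(lev)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  P <- matrix(0, ng, ng)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    for (k in seq_len(nrow(dirs))) {
      x2 <- x + dirs[k, 1]; y2 <- y + dirs[k, 2]; z2 <- z + dirs[k, 3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      lj <- lev[x2, y2, z2]
      if (lj == 0) next
      P[li, lj] <- P[li, lj] + 1
      P[lj, li] <- P[lj, li] + 1
    }
  }
  P
}

# Brute-force GLDM dependence counts.
bf_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  P <- matrix(0, ng, 27)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    li <- lev[x, y, z]
    if (li == 0) next
    dep <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      lj <- lev[x2, y2, z2]
      if (lj != 0 && abs(lj - li) <= alpha) dep <- dep + 1
    }
    P[li, dep + 1] <- P[li, dep + 1] + 1
  }
  P
}

# ICC(2,1) from a two-way ANOVA table fitted with aov() — an oracle
# independent of the package's closed-form implementation.
aov_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::aov(y ~ subj + rater, df))
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Weibull proportional-hazards cohort with administrative censoring.
simulate_ph_cohort <- function(n, hr, prevalence = 0.25, shape = 1.3,
                               scale = 60, censor = c(24, 84)) {
  grp <- rbinom(n, 1, prevalence)
  u <- runif(n)
  t <- scale * (-log(u) / exp(log(hr) * grp))^(1 / shape)
  cens <- runif(n, censor[1], censor[2])
  data.frame(time = pmin(t, cens), event = as.integer(t <= cens), grp = grp,
             group = factor(grp))
}
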