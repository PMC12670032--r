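# Per-class feature computations. Intensities are used raw for first-order
# statistics; texture classes operate on grey levels discretised with a fixed
# bin width (bins anchored at the ROI minimum). Texture matrices are
# accumulated in C++ over the 13 unique 3D directions (merged-matrix
# convention) and the scalar features are computed here.

# Fixed-bin-width discretisation; level 0 marks voxels outside the ROI.
discretize_roi <- function(vals, bin_width) {
  lev <- floor((vals - min(vals)) / bin_width) + 1L
  as.integer(lev)
}

fo_features <- function(x, voxel_volume, bin_width) {
  n <- length(x)
  p <- {
    lev <- discretize_roi(x, bin_width)
    tab <- tabulate(lev)
    tab[tab > 0] / n
  }
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  inr <- x[x >= qs[1] & x <= qs[5]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else NA_real_
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(inr - mean(inr))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}

# Shape from the binary mask alone (sequence-independent). Volume and surface
# use the voxel representation: volume = n * voxel volume, surface = exposed
# voxel faces; diameters from surface-voxel centre coordinates; axis lengths
# from the coordinate covariance eigenvalues (4*sqrt(lambda)).
shape_features <- function(roi, spacing) {
  d <- dim(roi)
  n <- sum(roi)
  vv <- prod(spacing)
  vol <- n * vv
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- roi
  exposed <- function(off, area) {
    shifted <- pad[(2:(d[1] + 1)) + off[1], (2:(d[2] + 1)) + off[2],
                   (2:(d[3] + 1)) + off[3], drop = FALSE]
    sum(roi & !shifted) * area
  }
  a_yz <- spacing[2] * spacing[3]
  a_xz <- spacing[1] * spacing[3]
  a_xy <- spacing[1] * spacing[2]
  surf <- exposed(c(1, 0, 0), a_yz) + exposed(c(-1, 0, 0), a_yz) +
    exposed(c(0, 1, 0), a_xz) + exposed(c(0, -1, 0), a_xz) +
    exposed(c(0, 0, 1), a_xy) + exposed(c(0, 0, -1), a_xy)

  idx <- which(roi)
  xyz <- voxel_coords_mm(idx, d, spacing)
  # surface voxels: at least one exposed face
  surf_mask <- roi & !(pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] &
                       pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE] &
                       pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1), drop = FALSE] &
                       pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1), drop = FALSE] &
                       pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3], drop = FALSE] &
                       pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2), drop = FALSE])
  sxyz <- voxel_coords_mm(which(surf_mask), d, spacing)

  maxdiam <- function(pts) {
    if (nrow(pts) < 2) return(0)
    max(dist(pts))
  }
  d3 <- maxdiam(sxyz)
  d_slice <- 0; d_col <- 0; d_row <- 0
  for (zz in unique(sxyz[, 3])) {
    d_slice <- max(d_slice, maxdiam(sxyz[sxyz[, 3] == zz, 1:2, drop = FALSE]))
  }
  for (yy in unique(sxyz[, 2])) {
    d_col <- max(d_col, maxdiam(sxyz[sxyz[, 2] == yy, c(1, 3), drop = FALSE]))
  }
  for (xx in unique(sxyz[, 1])) {
    d_row <- max(d_row, maxdiam(sxyz[sxyz[, 1] == xx, 2:3, drop = FALSE]))
  }

  if (n > 1) {
    cv <- stats::cov(xyz) * (n - 1) / n  # population covariance
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  c(MeshVolume = vol,
    VoxelVolume = vol,
    SurfaceArea = surf,
    SurfaceVolumeRatio = surf / vol,
    Sphericity = (36 * pi * vol^2)^(1 / 3) / surf,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_)
}

glcm_features <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) {
    return(setNames(rep(NA_real_, 24), FEATURE_MANIFEST$glcm))
  }
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)          # == mux == muy by symmetry
  sigma2 <- sum((i - mu)^2 * p)
  sigma <- sqrt(sigma2)
  # p_{x+y}, p_{x-y}
  ps_m <- rowsum(as.vector(p), as.vector(i + j))
  ks <- as.numeric(rownames(ps_m)); pxy_sum <- as.vector(ps_m)
  pd_m <- rowsum(as.vector(p), as.vector(abs(i - j)))
  kd <- as.numeric(rownames(pd_m)); pxy_dif <- as.vector(pd_m)
  eps <- .Machine$double.eps
  hxy <- -sum(p[p > 0] * log2(p[p > 0]))
  pipj <- px[i] * px[j]
  hxy1 <- -sum(p * log2(pipj + eps))
  hxy2 <- -sum(pipj[pipj > 0] * log2(pipj[pipj > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  da <- sum(kd * pxy_dif)
  corr <- if (sigma2 > 0) (sum(i * j * p) - mu^2) / sigma2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  mcc <- {
    # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)); MCC = sqrt(2nd eigenvalue)
    nzx <- px > 0
    if (sum(nzx) > 1) {
      psub <- p[nzx, nzx, drop = FALSE]
      pxs <- px[nzx]
      Qs <- sweep(psub, 1, pxs, "/") %*% t(sweep(psub, 2, pxs, "/"))
      evq <- sort(Re(eigen(Qs, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(evq[2], 0))
    } else 1
  }
  c(Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxy_dif[pxy_dif > 0] * log2(pxy_dif[pxy_dif > 0])),
    DifferenceVariance = sum((kd - da)^2 * pxy_dif),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum(ks * pxy_sum),
    SumEntropy = -sum(pxy_sum[pxy_sum > 0] * log2(pxy_sum[pxy_sum > 0])),
    SumSquares = sigma2)
}

glrlm_features <- function(P, n_vox, n_dir = 13) {
  nr <- sum(P)
  if (nr == 0) return(setNames(rep(NA_real_, 16), FEATURE_MANIFEST$glrlm))
  i <- row(P); j <- col(P)
  p <- P / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pg <- rowSums(P); pr <- colSums(P)
  c(GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    LongRunEmphasis = sum(P * j^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    RunLengthNonUniformity = sum(pr^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / nr^2,
    RunPercentage = nr / (n_vox * n_dir),
    RunVariance = sum((j - mu_j)^2 * p),
    ShortRunEmphasis = sum(P / j^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr)
}

glszm_features <- function(zones, n_vox) {
  # zones: 2-column matrix (level, size)
  if (nrow(zones) == 0) return(setNames(rep(NA_real_, 16), FEATURE_MANIFEST$glszm))
  nz <- nrow(zones)
  i <- zones[, 1]; s <- zones[, 2]
  p <- rep(1 / nz, nz)
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  pg <- tabulate(i)                     # zones per level
  ps <- tabulate(s)                     # zones per size
  pz <- rle(sort((i - 1) * (max(s) + 1L) + s))$lengths / nz
  c(GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    HighGrayLevelZoneEmphasis = sum(i^2) / nz,
    LargeAreaEmphasis = sum(s^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(i^2 * s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(s^2 / i^2) / nz,
    LowGrayLevelZoneEmphasis = sum(1 / i^2) / nz,
    SizeZoneNonUniformity = sum(ps^2) / nz,
    SizeZoneNonUniformityNormalized = sum(ps^2) / nz^2,
    SmallAreaEmphasis = sum(1 / s^2) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(i^2 / s^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (i^2 * s^2)) / nz,
    ZoneEntropy = -sum(pz * log2(pz)),
    ZonePercentage = nz / n_vox,
    ZoneVariance = sum((s - mu_s)^2 * p))
}

gldm_features <- function(P) {
  nz <- sum(P)
  if (nz == 0) return(setNames(rep(NA_real_, 14), FEATURE_MANIFEST$gldm))
  i <- row(P); j <- col(P)
  p <- P / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pg <- rowSums(P); pd <- colSums(P)
  c(DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    DependenceVariance = sum((j - mu_j)^2 * p),
    GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz)
}

ngtdm_features <- function(M, n_vox) {
  # M: ng x 2 matrix (n_i, s_i)
  n_i <- M[, 1]; s_i <- M[, 2]
  np <- sum(n_i)
  if (np == 0) return(setNames(rep(NA_real_, 5), FEATURE_MANIFEST$ngtdm))
  ivals <- seq_len(nrow(M))
  p_i <- n_i / np
  nz <- p_i > 0
  ngp <- sum(nz)
  iv <- ivals[nz]; pv <- p_i[nz]; sv <- s_i[nz]
  coarse_den <- sum(pv * sv)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    ii <- rep(iv, each = length(iv)); jj <- rep(iv, times = length(iv))
    pii <- rep(pv, each = length(pv)); pjj <- rep(pv, times = length(pv))
    sii <- rep(sv, each = length(sv)); sjj <- rep(sv, times = length(sv))
    contrast <- sum(pii * pjj * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(sv) / np
    busy_den <- sum(abs(ii * pii - jj * pjj))
    busyness <- if (busy_den > 0) coarse_den / busy_den else 0
    complexity <- sum(abs(ii - jj) * (pii * sii + pjj * sjj) / (pii + pjj)) / np
    strength <- if (sum(sv) > 0) sum((pii + pjj) * (ii - jj)^2) / sum(sv) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}
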