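# Feature-family implementations. Conventions: grey levels are the
# discretized integers 1..Ng; 0*log(0) = 0; undefined quantities return NaN
# and are flagged degenerate by the caller.

plog2 <- function(p) ifelse(p > 0, log2(p), 0)

firstorder_features <- function(v, voxvol_mm3, dz) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  p <- tabulate(dz$levels[dz$levels > 0], nbins = dz$n_levels) / n
  q <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  rsub <- v[v >= q[1] & v <= q[4]]
  c(Energy = sum(v^2),
    TotalEnergy = voxvol_mm3 * sum(v^2),
    Entropy = -sum(p * plog2(p)),
    Minimum = min(v),
    P10 = q[1], P90 = q[4],
    Maximum = max(v),
    Mean = m, Median = stats::median(v),
    InterquartileRange = q[3] - q[2],
    Range = max(v) - min(v),
    MeanAbsoluteDeviation = mean(abs(v - m)),
    RobustMeanAbsoluteDeviation = mean(abs(rsub - mean(rsub))),
    RootMeanSquared = sqrt(mean(v^2)),
    Skewness = if (m2 > 0) mean((v - m)^3) / m2^1.5 else NaN,
    Kurtosis = if (m2 > 0) mean((v - m)^4) / m2^2 else NaN,
    Variance = m2,
    Uniformity = sum(p^2))
}

# Shape features from the voxelised mask. Surface area and mesh volume use
# the voxel-boundary mesh (exposed voxel faces), so MeshVolume coincides
# with VoxelVolume and the surface is the staircase surface; exact for
# axis-aligned boxes, an overestimate for smooth bodies.
shape_features <- function(mask) {
  sp <- mask$geometry$spacing
  vox <- mask$voxels
  n <- sum(vox)
  voxvol <- prod(sp)
  V <- n * voxvol
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  sa <- 0
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    shifted <- shift_array(vox, d)
    shifted_m <- shift_array(vox, -d)
    sa <- sa + face_area[ax] * (sum(vox == 1L & shifted_m == 0L) +
                                  sum(vox == 1L & shifted == 0L))
  }
  idx <- which(vox == 1L, arr.ind = TRUE)
  pts <- cbind(axis_coords(mask$geometry, 1)[idx[, 1]],
               axis_coords(mask$geometry, 2)[idx[, 2]],
               axis_coords(mask$geometry, 3)[idx[, 3]])
  # boundary voxels (any exposed face) for the diameters
  expo <- array(FALSE, dim(vox))
  for (ax in 1:3) {
    d <- c(0L, 0L, 0L); d[ax] <- 1L
    expo <- expo | (vox == 1L & shift_array(vox, d) == 0L) |
      (vox == 1L & shift_array(vox, -d) == 0L)
  }
  bidx <- which(expo, arr.ind = TRUE)
  bp <- cbind(axis_coords(mask$geometry, 1)[bidx[, 1]],
              axis_coords(mask$geometry, 2)[bidx[, 2]],
              axis_coords(mask$geometry, 3)[bidx[, 3]])
  max_pair <- function(p, cols) {
    if (nrow(p) < 2) return(0)
    max(stats::dist(p[, cols, drop = FALSE]))
  }
  d3 <- max_pair(bp, 1:3)
  # per-plane 2-D diameters: slice = constant z (xy), column = constant y
  # (xz), row = constant x (yz)
  plane_max <- function(const_col, cols) {
    if (nrow(bp) < 2) return(0)
    mx <- 0
    for (u in unique(bp[, const_col])) {
      s <- bp[bp[, const_col] == u, , drop = FALSE]
      mx <- max(mx, max_pair(s, cols))
    }
    mx
  }
  cov_m <- if (n > 1) stats::cov(pts) * (n - 1) / n else matrix(0, 3, 3)
  ev <- sort(pmax(eigen(cov_m, symmetric = TRUE)$values, 0), decreasing = TRUE)
  c(MeshVolume = V,
    VoxelVolume = V,
    SurfaceArea = sa,
    SurfaceVolumeRatio = sa / V,
    Sphericity = (36 * pi * V^2)^(1 / 3) / sa,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = plane_max(3, 1:2),
    Maximum2DDiameterColumn = plane_max(2, c(1, 3)),
    Maximum2DDiameterRow = plane_max(1, 2:3),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NaN,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NaN)
}

glcm_matrix <- function(dz) {
  cpp_glcm(dz$levels, dim(dz$levels), dz$n_levels)
}

glcm_features <- function(dz) {
  ng <- dz$n_levels
  nm <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
          "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
          "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn",
          "Idn", "Imc1", "Imc2", "InverseVariance", "JointAverage",
          "JointEnergy", "JointEntropy", "MCC", "MaximumProbability",
          "SumAverage", "SumEntropy", "SumSquares")
  if (ng < 2) return(stats::setNames(rep(NaN, 24), nm))
  M <- glcm_matrix(dz)
  i_idx <- matrix(rep(1:ng, ng), ng, ng)
  j_idx <- t(i_idx)
  acc <- matrix(0, length(nm), 13, dimnames = list(nm, NULL))
  for (d in 1:13) {
    P <- M[, , d]
    tot <- sum(P)
    if (tot == 0) { acc[, d] <- NaN; next }
    p <- P / tot
    px <- rowSums(p); py <- colSums(p)
    mux <- sum(1:ng * px); muy <- sum(1:ng * py)
    sx <- sqrt(sum((1:ng - mux)^2 * px)); sy <- sqrt(sum((1:ng - muy)^2 * py))
    # diagonal (difference) and cross (sum) marginals
    k_diff <- 0:(ng - 1)
    p_diff <- vapply(k_diff, function(k) sum(p[abs(i_idx - j_idx) == k]), 0.0)
    k_sum <- 2:(2 * ng)
    p_sum <- vapply(k_sum, function(k) sum(p[(i_idx + j_idx) == k]), 0.0)
    da <- sum(k_diff * p_diff)
    hxy <- -sum(p * plog2(p))
    pxy <- outer(px, py)
    hxy1 <- -sum(p * plog2(pxy))
    hxy2 <- -sum(pxy * plog2(pxy))
    hx <- -sum(px * plog2(px)); hy <- -sum(py * plog2(py))
    imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NaN
    imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
    # MCC: sqrt of the second-largest eigenvalue of Q
    mcc <- NaN
    pos <- px > 0
    if (sum(pos) > 1) {
      Q <- matrix(0, ng, ng)
      denom <- outer(px, py)
      for (kk in 1:ng) {
        if (py[kk] == 0) next
        Q <- Q + outer(p[, kk], p[, kk]) / outer(px, rep(py[kk], ng))
      }
      Q[!is.finite(Q)] <- 0
      evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      mcc <- sqrt(pmax(0, evq[2]))
    }
    acc["Autocorrelation", d] <- sum(i_idx * j_idx * p)
    acc["ClusterProminence", d] <- sum((i_idx + j_idx - mux - muy)^4 * p)
    acc["ClusterShade", d] <- sum((i_idx + j_idx - mux - muy)^3 * p)
    acc["ClusterTendency", d] <- sum((i_idx + j_idx - mux - muy)^2 * p)
    acc["Contrast", d] <- sum((i_idx - j_idx)^2 * p)
    acc["Correlation", d] <- if (sx > 0 && sy > 0)
      (sum(i_idx * j_idx * p) - mux * muy) / (sx * sy) else NaN
    acc["DifferenceAverage", d] <- da
    acc["DifferenceEntropy", d] <- -sum(p_diff * plog2(p_diff))
    acc["DifferenceVariance", d] <- sum((k_diff - da)^2 * p_diff)
    acc["Id", d] <- sum(p / (1 + abs(i_idx - j_idx)))
    acc["Idm", d] <- sum(p / (1 + (i_idx - j_idx)^2))
    acc["Idmn", d] <- sum(p / (1 + (i_idx - j_idx)^2 / ng^2))
    acc["Idn", d] <- sum(p / (1 + abs(i_idx - j_idx) / ng))
    acc["Imc1", d] <- imc1
    acc["Imc2", d] <- imc2
    acc["InverseVariance", d] <- sum(p[i_idx != j_idx] /
                                       (i_idx - j_idx)[i_idx != j_idx]^2)
    acc["JointAverage", d] <- mux
    acc["JointEnergy", d] <- sum(p^2)
    acc["JointEntropy", d] <- hxy
    acc["MCC", d] <- mcc
    acc["MaximumProbability", d] <- max(p)
    acc["SumAverage", d] <- sum(k_sum * p_sum)
    acc["SumEntropy", d] <- -sum(p_sum * plog2(p_sum))
    acc["SumSquares", d] <- sum((i_idx - mux)^2 * p)
  }
  rowMeans(acc)
}

rlm_style_features <- function(P, np, names_map) {
  # shared formulas for run-length (P: level x length) and size-zone
  # matrices; names_map translates the generic names to the family's.
  ng <- nrow(P); nl <- ncol(P)
  nr <- sum(P)
  if (nr == 0) return(stats::setNames(rep(NaN, length(names_map)),
                                      unname(names_map)))
  i <- matrix(rep(1:ng, nl), ng, nl)
  l <- matrix(rep(1:nl, each = ng), ng, nl)
  p <- P / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  vals <- c(
    GLN = sum(rowSums(P)^2) / nr,
    GLNN = sum(rowSums(P)^2) / nr^2,
    GLV = sum((i - mu_i)^2 * p),
    HGL = sum(P * i^2) / nr,
    Long = sum(P * l^2) / nr,
    LongHGL = sum(P * i^2 * l^2) / nr,
    LongLGL = sum(P * l^2 / i^2) / nr,
    LGL = sum(P / i^2) / nr,
    Entropy = -sum(p * plog2(p)),
    LN = sum(colSums(P)^2) / nr,
    LNN = sum(colSums(P)^2) / nr^2,
    Percentage = nr / np,
    LV = sum((l - mu_l)^2 * p),
    Short = sum(P / l^2) / nr,
    ShortHGL = sum(P * i^2 / l^2) / nr,
    ShortLGL = sum(P / (i^2 * l^2)) / nr)
  stats::setNames(vals[names(names_map)], unname(names_map))
}

glrlm_features <- function(dz) {
  nm <- c(GLN = "GrayLevelNonUniformity",
          GLNN = "GrayLevelNonUniformityNormalized",
          GLV = "GrayLevelVariance", HGL = "HighGrayLevelRunEmphasis",
          Long = "LongRunEmphasis", LongHGL = "LongRunHighGrayLevelEmphasis",
          LongLGL = "LongRunLowGrayLevelEmphasis",
          LGL = "LowGrayLevelRunEmphasis", Entropy = "RunEntropy",
          LN = "RunLengthNonUniformity",
          LNN = "RunLengthNonUniformityNormalized", Percentage = "RunPercentage",
          LV = "RunVariance", Short = "ShortRunEmphasis",
          ShortHGL = "ShortRunHighGrayLevelEmphasis",
          ShortLGL = "ShortRunLowGrayLevelEmphasis")
  if (dz$n_levels < 2)
    return(stats::setNames(rep(NaN, 16), unname(nm)))
  M <- cpp_glrlm(dz$levels, dim(dz$levels), dz$n_levels)
  np <- sum(dz$levels > 0)
  acc <- vapply(1:13, function(d)
    rlm_style_features(matrix(M[, , d], dim(M)[1], dim(M)[2]), np, nm),
    numeric(16))
  rowMeans(acc)
}

glszm_features <- function(dz) {
  nm <- c(GLN = "GrayLevelNonUniformity",
          GLNN = "GrayLevelNonUniformityNormalized",
          GLV = "GrayLevelVariance", HGL = "HighGrayLevelZoneEmphasis",
          Long = "LargeAreaEmphasis", LongHGL = "LargeAreaHighGrayLevelEmphasis",
          LongLGL = "LargeAreaLowGrayLevelEmphasis",
          LGL = "LowGrayLevelZoneEmphasis", LN = "SizeZoneNonUniformity",
          LNN = "SizeZoneNonUniformityNormalized",
          Short = "SmallAreaEmphasis", ShortHGL = "SmallAreaHighGrayLevelEmphasis",
          ShortLGL = "SmallAreaLowGrayLevelEmphasis", Entropy = "ZoneEntropy",
          Percentage = "ZonePercentage", LV = "ZoneVariance")
  if (dz$n_levels < 2)
    return(stats::setNames(rep(NaN, 16), unname(nm)))
  zones <- cpp_glszm(dz$levels, dim(dz$levels), dz$n_levels)
  np <- sum(dz$levels > 0)
  maxs <- max(zones[, 2])
  P <- matrix(0, dz$n_levels, maxs)
  for (r in seq_len(nrow(zones))) {
    P[zones[r, 1], zones[r, 2]] <- P[zones[r, 1], zones[r, 2]] + 1
  }
  rlm_style_features(P, np, nm)
}

ngtdm_features <- function(dz) {
  nm <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  if (dz$n_levels < 2) return(stats::setNames(rep(NaN, 5), nm))
  M <- cpp_ngtdm(dz$levels, dim(dz$levels), dz$n_levels)
  n_i <- M[, 1]; s_i <- M[, 2]
  nvc <- sum(n_i)
  if (nvc == 0) return(stats::setNames(rep(NaN, 5), nm))
  p_i <- n_i / nvc
  act <- which(p_i > 0)
  ngp <- length(act)
  iv <- seq_len(dz$n_levels)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    pij_d2 <- outer(p_i[act], p_i[act]) * outer(iv[act], iv[act], "-")^2
    contrast <- sum(pij_d2) / (ngp * (ngp - 1)) * sum(s_i) / nvc
    busy_den <- sum(abs(outer(iv[act] * p_i[act], iv[act] * p_i[act], "-")))
    busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else NaN
    cplx <- 0
    str_num <- 0
    for (a in act) for (b in act) {
      cplx <- cplx + abs(a - b) * (p_i[a] * s_i[a] + p_i[b] * s_i[b]) /
        (p_i[a] + p_i[b])
      str_num <- str_num + (p_i[a] + p_i[b]) * (a - b)^2
    }
    complexity <- cplx / nvc
    strength <- if (sum(s_i) > 0) str_num / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  stats::setNames(c(busyness, coarseness, complexity, contrast, strength), nm)
}

gldm_features <- function(dz, alpha = 0L) {
  nm <- c("DependenceEntropy", "DependenceNonUniformity",
          "DependenceNonUniformityNormalized", "DependenceVariance",
          "GrayLevelNonUniformity", "GrayLevelVariance",
          "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
          "LargeDependenceHighGrayLevelEmphasis",
          "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
          "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
          "SmallDependenceLowGrayLevelEmphasis")
  if (dz$n_levels < 2) return(stats::setNames(rep(NaN, 14), nm))
  P <- cpp_gldm(dz$levels, dim(dz$levels), dz$n_levels, as.integer(alpha))
  nz <- sum(P)
  ng <- nrow(P); nd <- ncol(P)
  i <- matrix(rep(1:ng, nd), ng, nd)
  j <- matrix(rep(1:nd, each = ng), ng, nd)
  p <- P / nz
  mu_j <- sum(j * p); mu_i <- sum(i * p)
  stats::setNames(c(
    -sum(p * plog2(p)),
    sum(colSums(P)^2) / nz,
    sum(colSums(P)^2) / nz^2,
    sum((j - mu_j)^2 * p),
    sum(rowSums(P)^2) / nz,
    sum((i - mu_i)^2 * p),
    sum(P * i^2) / nz,
    sum(P * j^2) / nz,
    sum(P * i^2 * j^2) / nz,
    sum(P * j^2 / i^2) / nz,
    sum(P / i^2) / nz,
    sum(P / j^2) / nz,
    sum(P * i^2 / j^2) / nz,
    sum(P / (i^2 * j^2)) / nz), nm)
}
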