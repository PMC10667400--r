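# Texture features from the five matrix families (75 features total:
# GLCM 24, GLDM 14, GLRLM 16, GLSZM 16, NGTDM 5).
#
# GLCM and GLRLM features are computed per direction and then averaged over
# the 13 directions. Entropies are in bits and sum over positive entries
# only. Degenerate single-gray-level ROIs use documented conventions:
# entropy 0, Imc1 = Imc2 = 0, Correlation = MCC = 1, NGTDM Contrast 0,
# Busyness/Strength 0 when their denominators vanish, Coarseness 1e6 when
# its denominator vanishes.

entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

# features of a single normalized, symmetric GLCM with level values `iv`
glcm_features_one <- function(p, iv) {
  ng <- length(iv)
  px <- rowSums(p)                  # == colSums by symmetry
  mu_x <- sum(iv * px)
  sig_x <- sqrt(sum((iv - mu_x)^2 * px))
  I <- matrix(iv, ng, ng)
  J <- t(I)
  # p_{x+y}: k = i + j ranges over 2..2*max; p_{x-y}: k = |i-j|
  ks <- as.vector(I + J)
  kd <- as.vector(abs(I - J))
  pv <- as.vector(p)
  psum <- rowsum(pv, ks)     # names = k values
  pdif <- rowsum(pv, kd)
  ksv <- as.numeric(rownames(psum))
  kdv <- as.numeric(rownames(pdif))
  psum <- psum[, 1]; pdif <- pdif[, 1]
  da <- sum(kdv * pdif)
  hx <- entropy_bits(px)
  hxy <- entropy_bits(pv)
  pxpy <- as.vector(outer(px, px))
  pos <- pv > 0 & pxpy > 0
  hxy1 <- if (any(pos)) -sum(pv[pos] * log2(pxpy[pos])) else 0
  hxy2 <- entropy_bits(pxpy)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  arg <- 1 - exp(-2 * (hxy2 - hxy))
  imc2 <- if (arg > 0) sqrt(arg) else 0
  corr <- if (sig_x > 0)
    (sum(I * J * p) - mu_x^2) / sig_x^2 else 1
  # MCC: second largest eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k)/(px(i) px(k))
  mcc <- 1
  if (ng > 1 && all(px > 0)) {
    Q <- matrix(0, ng, ng)
    for (kk in seq_len(ng)) {
      Q <- Q + outer(p[, kk] / px, p[, kk]) / px[kk]
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, ev[min(2, length(ev))]))
  }
  c(
    Autocorrelation = sum(I * J * p),
    JointAverage = mu_x,
    ClusterProminence = sum((I + J - 2 * mu_x)^4 * p),
    ClusterShade = sum((I + J - 2 * mu_x)^3 * p),
    ClusterTendency = sum((I + J - 2 * mu_x)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy_bits(pdif),
    DifferenceVariance = sum((kdv - da)^2 * pdif),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (I - J)^2)),
    Idmn = sum(p / (1 + ((I - J) / ng)^2)),
    Id = sum(p / (1 + abs(I - J))),
    Idn = sum(p / (1 + abs(I - J) / ng)),
    InverseVariance = sum(pdif[kdv > 0] / kdv[kdv > 0]^2),
    MaximumProbability = max(p),
    SumAverage = sum(ksv * psum),
    SumEntropy = entropy_bits(psum),
    SumSquares = sum((I - mu_x)^2 * p),
    MCC = mcc
  )
}

#' GLCM features (24), averaged over the 13 directions
#' @param glcm Output of [glcm_matrices()].
#' @return Named numeric vector, names prefixed "GLCM_".
#' @export
glcm_features <- function(glcm) {
  per <- vapply(glcm$p, glcm_features_one, numeric(24), iv = glcm$levels)
  out <- rowMeans(per)
  names(out) <- paste0("GLCM_", names(out))
  out
}

# run-length style features shared by GLRLM (per direction) and GLSZM
# m: count matrix level x size; iv: level values; np: voxel count
rl_features_one <- function(m, iv, np) {
  nr <- sum(m)
  jv <- seq_len(ncol(m))
  ri <- rowSums(m)           # per-level totals
  rj <- colSums(m)           # per-size totals
  I2 <- iv^2
  J2 <- jv^2
  p <- m / nr
  mu_i <- sum(iv * rowSums(p))
  mu_j <- sum(jv * colSums(p))
  vals <- c(
    ShortEmphasis = sum(rj / J2) / nr,
    LongEmphasis = sum(rj * J2) / nr,
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    SizeNonUniformity = sum(rj^2) / nr,
    SizeNonUniformityNormalized = sum(rj^2) / nr^2,
    Percentage = nr / np,
    GrayLevelVariance = sum(outer(((iv - mu_i)^2), rep(1, ncol(m))) * p),
    SizeVariance = sum(outer(rep(1, nrow(m)), ((jv - mu_j)^2)) * p),
    Entropy = entropy_bits(as.vector(p)),
    LowGrayLevelEmphasis = sum(ri / I2) / nr,
    HighGrayLevelEmphasis = sum(ri * I2) / nr,
    ShortLowGrayLevelEmphasis = sum(outer(1 / I2, 1 / J2) * m) / nr,
    ShortHighGrayLevelEmphasis = sum(outer(I2, 1 / J2) * m) / nr,
    LongLowGrayLevelEmphasis = sum(outer(1 / I2, J2) * m) / nr,
    LongHighGrayLevelEmphasis = sum(outer(I2, J2) * m) / nr
  )
  vals
}

#' GLRLM features (16), averaged over the 13 directions
#' @param glrlm Output of [glrlm_matrices()].
#' @return Named numeric vector, names prefixed "GLRLM_".
#' @export
glrlm_features <- function(glrlm) {
  per <- vapply(glrlm$p, rl_features_one, numeric(16),
                iv = glrlm$levels, np = glrlm$n_voxels)
  out <- rowMeans(per)
  names(out) <- paste0("GLRLM_", c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
  out
}

#' GLSZM features (16)
#' @param glszm Output of [glszm_matrix()].
#' @return Named numeric vector, names prefixed "GLSZM_".
#' @export
glszm_features <- function(glszm) {
  v <- rl_features_one(glszm$p, glszm$levels, glszm$n_voxels)
  names(v) <- paste0("GLSZM_", c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage",
    "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
  v
}

#' GLDM features (14)
#'
#' Same functional forms as the run-length family over (gray level,
#' dependence), normalized by the voxel count; no normalized gray-level
#' non-uniformity variant in this family.
#'
#' @param gldm Output of [gldm_matrix()].
#' @return Named numeric vector, names prefixed "GLDM_".
#' @export
gldm_features <- function(gldm) {
  v <- rl_features_one(gldm$p, gldm$levels, gldm$n_voxels)
  keep <- setdiff(names(v), c("GrayLevelNonUniformityNormalized", "Percentage"))
  v <- v[keep]
  names(v) <- paste0("GLDM_", c(
    "SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized",
    "GrayLevelVariance", "DependenceVariance", "DependenceEntropy",
    "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis"))
  v
}

#' NGTDM features (5)
#' @param ng Output of [ngtdm_matrix()].
#' @return Named numeric vector, names prefixed "NGTDM_".
#' @export
ngtdm_features <- function(ng) {
  iv <- ng$levels; p <- ng$p_i; s <- ng$s_i; nvp <- ng$n_vp
  pos <- p > 0
  ngp <- sum(pos)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  if (ngp > 1) {
    dI <- outer(iv[pos], iv[pos], "-")
    contrast <- sum(outer(p[pos], p[pos]) * dI^2) /
      (ngp * (ngp - 1)) * sum(s) / nvp
    ipi <- iv[pos] * p[pos]
    # pair sums below run over ordered pairs (i, j), both orders
    denb <- sum(abs(outer(ipi, ipi, "-")))
    busyness <- if (denb > 0) ps / denb else 0
    pm <- outer(p[pos], p[pos], "+")
    sm <- outer(p[pos] * s[pos], p[pos] * s[pos], "+")
    complexity <- sum(abs(dI) * sm / pm) / nvp
    strength <- if (sum(s) > 0) sum(pm * dI^2) / sum(s) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  out <- c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
           Complexity = complexity, Strength = strength)
  names(out) <- paste0("NGTDM_", names(out))
  out
}

#' All 75 texture features from prebuilt matrices
#' @param mats Output of [build_matrices()].
#' @return Named numeric vector of 75 values.
#' @export
texture_features <- function(mats) {
  c(glcm_features(mats$glcm),
    gldm_features(mats$gldm),
    glrlm_features(mats$glrlm),
    glszm_features(mats$glszm),
    ngtdm_features(mats$ngtdm))
}
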