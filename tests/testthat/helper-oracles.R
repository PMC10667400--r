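# Independent brute-force oracles. These deliberately use naive loops and a
# separate coding of every formula; they are slow and only ever run on tiny
# inputs. They must never call the package's vectorized builders.

# --- texture matrix oracles -------------------------------------------------

oracle_offsets <- function() {
  offs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    o <- c(dx, dy, dz)
    if (all(o == 0)) next
    nz <- o[o != 0]
    if (nz[1] > 0) offs[[length(offs) + 1]] <- o
  }
  do.call(rbind, offs)
}

in_grid <- function(p, dims) all(p >= 1) && all(p <= dims)

# symmetrized normalized GLCM for one offset; levels indexed by values present
oracle_glcm_one <- function(lev, mask, o, present) {
  dims <- dim(lev)
  ng <- length(present)
  m <- matrix(0, ng, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    q <- c(x, y, z) + o
    if (!in_grid(q, dims)) next
    if (!mask[q[1], q[2], q[3]]) next
    i <- match(lev[x, y, z], present)
    j <- match(lev[q[1], q[2], q[3]], present)
    m[i, j] <- m[i, j] + 1
    m[j, i] <- m[j, i] + 1
  }
  if (sum(m) > 0) m / sum(m) else m
}

# GLRLM for one direction by explicit line walking
oracle_glrlm_one <- function(lev, mask, o, present) {
  dims <- dim(lev)
  ng <- length(present)
  runs <- list()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    p <- c(x, y, z)
    if (!mask[x, y, z]) next
    prev <- p - o
    # run starts here if predecessor is not a same-level in-mask voxel
    if (in_grid(prev, dims) && mask[prev[1], prev[2], prev[3]] &&
        lev[prev[1], prev[2], prev[3]] == lev[x, y, z]) next
    len <- 1
    q <- p + o
    while (in_grid(q, dims) && mask[q[1], q[2], q[3]] &&
           lev[q[1], q[2], q[3]] == lev[x, y, z]) {
      len <- len + 1
      q <- q + o
    }
    runs[[length(runs) + 1]] <- c(match(lev[x, y, z], present), len)
  }
  maxlen <- max(vapply(runs, `[`, numeric(1), 2))
  m <- matrix(0, ng, maxlen)
  for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1
  m
}

# GLSZM by recursive flood fill over the 26-neighborhood
oracle_glszm <- function(lev, mask, present) {
  dims <- dim(lev)
  ng <- length(present)
  seen <- array(FALSE, dims)
  sizes <- c(); levels <- c()
  offs26 <- rbind(oracle_offsets(), -oracle_offsets())
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z] || seen[x, y, z]) next
    target <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (k in seq_len(nrow(offs26))) {
        q <- p + offs26[k, ]
        if (!in_grid(q, dims)) next
        if (seen[q[1], q[2], q[3]] || !mask[q[1], q[2], q[3]]) next
        if (lev[q[1], q[2], q[3]] != target) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1]] <- q
      }
    }
    sizes <- c(sizes, size); levels <- c(levels, match(target, present))
  }
  m <- matrix(0, ng, max(sizes))
  for (i in seq_along(sizes)) m[levels[i], sizes[i]] <- m[levels[i], sizes[i]] + 1
  m
}

oracle_gldm <- function(lev, mask, present, alpha = 0) {
  dims <- dim(lev)
  ng <- length(present)
  offs26 <- rbind(oracle_offsets(), -oracle_offsets())
  deps <- c(); levs <- c()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    dep <- 1
    for (k in seq_len(nrow(offs26))) {
      q <- c(x, y, z) + offs26[k, ]
      if (!in_grid(q, dims) || !mask[q[1], q[2], q[3]]) next
      if (abs(lev[q[1], q[2], q[3]] - lev[x, y, z]) <= alpha) dep <- dep + 1
    }
    deps <- c(deps, dep); levs <- c(levs, match(lev[x, y, z], present))
  }
  m <- matrix(0, ng, max(deps))
  for (i in seq_along(deps)) m[levs[i], deps[i]] <- m[levs[i], deps[i]] + 1
  m
}

oracle_ngtdm <- function(lev, mask) {
  dims <- dim(lev)
  offs26 <- rbind(oracle_offsets(), -oracle_offsets())
  xs <- c(); ds <- c()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    nb <- c()
    for (k in seq_len(nrow(offs26))) {
      q <- c(x, y, z) + offs26[k, ]
      if (!in_grid(q, dims) || !mask[q[1], q[2], q[3]]) next
      nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (!length(nb)) next
    xs <- c(xs, lev[x, y, z])
    ds <- c(ds, abs(lev[x, y, z] - mean(nb)))
  }
  present <- sort(unique(xs))
  n_i <- sapply(present, function(l) sum(xs == l))
  s_i <- sapply(present, function(l) sum(ds[xs == l]))
  list(levels = present, n_i = n_i, p_i = n_i / sum(n_i), s_i = s_i,
       n_vp = sum(n_i))
}

# --- texture feature oracles (explicit sums from the definitions) -----------

oracle_glcm_features_one <- function(p, iv) {
  ng <- length(iv)
  px <- sapply(1:ng, function(i) sum(p[i, ]))
  mu <- 0; for (i in 1:ng) for (j in 1:ng) mu <- mu + iv[i] * p[i, j]
  sig2 <- 0; for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (iv[i] - mu)^2 * p[i, j]
  f <- list()
  f$Autocorrelation <- sum(sapply(1:ng, function(i)
    sum(sapply(1:ng, function(j) iv[i] * iv[j] * p[i, j]))))
  f$JointAverage <- mu
  for (pw in 2:4) {
    v <- 0
    for (i in 1:ng) for (j in 1:ng)
      v <- v + (iv[i] + iv[j] - 2 * mu)^pw * p[i, j]
    f[[c("ClusterTendency", "ClusterShade", "ClusterProminence")[pw - 1]]] <- v
  }
  v <- 0; for (i in 1:ng) for (j in 1:ng) v <- v + (iv[i] - iv[j])^2 * p[i, j]
  f$Contrast <- v
  f$Correlation <- if (sig2 > 0) (f$Autocorrelation - mu^2) / sig2 else 1
  kd <- sort(unique(as.vector(abs(outer(iv, iv, "-")))))
  pd <- sapply(kd, function(k) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (abs(iv[i] - iv[j]) == k) s <- s + p[i, j]
    s
  })
  f$DifferenceAverage <- sum(kd * pd)
  f$DifferenceEntropy <- -sum(ifelse(pd > 0, pd * log2(pd), 0))
  f$DifferenceVariance <- sum((kd - f$DifferenceAverage)^2 * pd)
  f$JointEnergy <- sum(p^2)
  f$JointEntropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * px[j]
    if (p[i, j] > 0 && q > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
    if (q > 0) hxy2 <- hxy2 - q * log2(q)
  }
  f$Imc1 <- if (hx > 0) (f$JointEntropy - hxy1) / hx else 0
  a <- 1 - exp(-2 * (hxy2 - f$JointEntropy))
  f$Imc2 <- if (a > 0) sqrt(a) else 0
  idm <- 0; idmn <- 0; id <- 0; idn <- 0; iv2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    d <- iv[i] - iv[j]
    idm <- idm + p[i, j] / (1 + d^2)
    idmn <- idmn + p[i, j] / (1 + (d / ng)^2)
    id <- id + p[i, j] / (1 + abs(d))
    idn <- idn + p[i, j] / (1 + abs(d) / ng)
    if (d != 0) iv2 <- iv2 + p[i, j] / d^2
  }
  f$Idm <- idm; f$Idmn <- idmn; f$Id <- id; f$Idn <- idn
  f$InverseVariance <- iv2
  f$MaximumProbability <- max(p)
  ks <- sort(unique(as.vector(outer(iv, iv, "+"))))
  ps <- sapply(ks, function(k) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (iv[i] + iv[j] == k) s <- s + p[i, j]
    s
  })
  f$SumAverage <- sum(ks * ps)
  f$SumEntropy <- -sum(ifelse(ps > 0, ps * log2(ps), 0))
  v <- 0; for (i in 1:ng) for (j in 1:ng) v <- v + (iv[i] - mu)^2 * p[i, j]
  f$SumSquares <- v
  if (ng > 1 && all(px > 0)) {
    Q <- matrix(0, ng, ng)
    for (i in 1:ng) for (j in 1:ng) for (k in 1:ng)
      Q[i, j] <- Q[i, j] + p[i, k] * p[j, k] / (px[i] * px[k])
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    f$MCC <- sqrt(max(0, ev[2]))
  } else f$MCC <- 1
  unlist(f)
}

# shared run-length/size-zone/dependence feature oracle from a count matrix
oracle_rlm_features <- function(m, iv, np) {
  nr <- sum(m)
  ni <- nrow(m); nj <- ncol(m)
  g <- function(fun) {
    s <- 0
    for (i in 1:ni) for (j in 1:nj) if (m[i, j] > 0) s <- s + fun(iv[i], j, m[i, j])
    s
  }
  p <- m / nr
  mu_i <- g(function(i, j, c) i * c / nr)
  mu_j <- g(function(i, j, c) j * c / nr)
  c(ShortEmphasis = g(function(i, j, c) c / j^2) / nr,
    LongEmphasis = g(function(i, j, c) c * j^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(m)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(m)^2) / nr^2,
    SizeNonUniformity = sum(colSums(m)^2) / nr,
    SizeNonUniformityNormalized = sum(colSums(m)^2) / nr^2,
    Percentage = nr / np,
    GrayLevelVariance = g(function(i, j, c) (i - mu_i)^2 * c / nr),
    SizeVariance = g(function(i, j, c) (j - mu_j)^2 * c / nr),
    Entropy = -g(function(i, j, c) {
      q <- c / nr; q * log2(q)
    }),
    LowGrayLevelEmphasis = g(function(i, j, c) c / i^2) / nr,
    HighGrayLevelEmphasis = g(function(i, j, c) c * i^2) / nr,
    ShortLowGrayLevelEmphasis = g(function(i, j, c) c / (i^2 * j^2)) / nr,
    ShortHighGrayLevelEmphasis = g(function(i, j, c) c * i^2 / j^2) / nr,
    LongLowGrayLevelEmphasis = g(function(i, j, c) c * j^2 / i^2) / nr,
    LongHighGrayLevelEmphasis = g(function(i, j, c) c * i^2 * j^2) / nr)
}

oracle_ngtdm_features <- function(o) {
  iv <- o$levels; p <- o$p_i; s <- o$s_i; nvp <- o$n_vp
  ngp <- sum(p > 0)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  if (ngp > 1) {
    for (i in seq_along(iv)) for (j in seq_along(iv)) {
      if (p[i] == 0 || p[j] == 0) next
      contrast <- contrast + p[i] * p[j] * (iv[i] - iv[j])^2
      busy_den <- busy_den + abs(iv[i] * p[i] - iv[j] * p[j])
      complexity <- complexity +
        abs(iv[i] - iv[j]) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      strength <- strength + (p[i] + p[j]) * (iv[i] - iv[j])^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / nvp
    complexity <- complexity / nvp
    strength <- if (sum(s) > 0) strength / sum(s) else 0
  }
  busy <- if (ngp > 1 && busy_den > 0) ps / busy_den else 0
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = complexity, Strength = strength)
}

# full 75-feature texture oracle from a discretized ROI
oracle_texture_features <- function(lev, mask) {
  present <- sort(unique(lev[mask]))
  offs <- oracle_offsets()
  glcm_per <- sapply(seq_len(nrow(offs)), function(k)
    oracle_glcm_features_one(oracle_glcm_one(lev, mask, offs[k, ], present),
                             present))
  glcm <- rowMeans(glcm_per)
  names(glcm) <- paste0("GLCM_", names(glcm))
  np <- sum(mask)
  glrlm_per <- sapply(seq_len(nrow(offs)), function(k)
    oracle_rlm_features(oracle_glrlm_one(lev, mask, offs[k, ], present),
                        present, np))
  glrlm <- rowMeans(glrlm_per)
  names(glrlm) <- paste0("GLRLM_", c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
    "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
    "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LongRunHighGrayLevelEmphasis"))
  szm <- oracle_rlm_features(oracle_glszm(lev, mask, present), present, np)
  names(szm) <- paste0("GLSZM_", c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
    "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
    "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LargeAreaHighGrayLevelEmphasis"))
  dl <- oracle_rlm_features(oracle_gldm(lev, mask, present), present, np)
  dl <- dl[setdiff(names(dl), c("GrayLevelNonUniformityNormalized",
                                "Percentage"))]
  names(dl) <- paste0("GLDM_", c(
    "SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "GrayLevelVariance",
    "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis"))
  ngt <- oracle_ngtdm_features(oracle_ngtdm(lev, mask))
  names(ngt) <- paste0("NGTDM_", names(ngt))
  c(glcm, dl, glrlm, szm, ngt)
}

# --- statistics oracles -----------------------------------------------------

# two-way ANOVA ICC(2,1) via explicit sums of squares
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  mu <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - mu)^2)
  ss_cols <- n * sum((colMeans(m) - mu)^2)
  ss_tot <- sum((m - mu)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# step-up BH by literal definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exact two-sided MWU p by enumerating all rank assignments
oracle_mwu_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  u_obs <- sum(r[1:nx]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(ix) sum(ix) - nx * (nx + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Kruskal-Wallis H by literal rank sums (no tie correction separate check)
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  grp <- rep(seq_along(groups), sizes)
  h <- 12 / (n * (n + 1)) *
    sum(sapply(seq_along(groups), function(g) sum(r[grp == g])^2 / sizes[g])) -
    3 * (n + 1)
  tie_tab <- table(x)
  h / (1 - sum(tie_tab^3 - tie_tab) / (n^3 - n))
}

# first-order oracle: independent coding with explicit formulas
oracle_first_order <- function(vol, mask, lev, ng, spacing) {
  x <- sort(vol[mask])
  n <- length(x)
  mu <- sum(x) / n
  cm <- function(k) sum((x - mu)^k) / n
  pct <- function(q) {          # type-7 linear interpolation, by hand
    h <- (n - 1) * q
    lo <- floor(h) + 1
    hi <- ceiling(h) + 1
    x[lo] + (h - floor(h)) * (x[hi] - x[lo])
  }
  p10 <- pct(0.10); p90 <- pct(0.90)
  inner <- x[x >= p10 & x <= p90]
  counts <- sapply(seq_len(ng), function(l) sum(lev[mask] == l))
  pr <- counts[counts > 0] / n
  c(FO_Energy = sum(x^2),
    FO_TotalEnergy = prod(spacing) * sum(x^2),
    FO_Entropy = -sum(pr * log2(pr)),
    FO_Minimum = x[1],
    `FO_10Percentile` = p10,
    `FO_90Percentile` = p90,
    FO_Maximum = x[n],
    FO_Mean = mu,
    FO_Median = if (n %% 2) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2,
    FO_InterquartileRange = pct(0.75) - pct(0.25),
    FO_Range = x[n] - x[1],
    FO_MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    FO_RobustMeanAbsoluteDeviation =
      sum(abs(inner - mean(inner))) / length(inner),
    FO_RootMeanSquared = sqrt(sum(x^2) / n),
    FO_Skewness = if (cm(2) > 0) cm(3) / cm(2)^1.5 else 0,
    FO_Kurtosis = if (cm(2) > 0) cm(4) / cm(2)^2 else 0,
    FO_Variance = cm(2),
    FO_Uniformity = sum(pr^2))
}
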