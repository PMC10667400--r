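# Texture matrix construction from a discretized ROI.
#
# All neighborhoods are at Chebyshev distance 1 (the 26-neighborhood in 3D);
# GLCM and GLRLM are built per direction over the 13 unique 3D offsets and
# kept per-direction (features are computed per direction, then averaged).
# Gray levels are the integer levels 1..ng of the discretized ROI; matrices
# are indexed over the levels actually present in the ROI, and feature
# formulas use the level VALUES, not their ranks, matching the convention of
# the standard extraction tooling.

#' The 13 unique 3D offsets at Chebyshev distance 1
#'
#' One representative per +/- pair of the 26-neighborhood.
#' @return 13 x 3 integer matrix (dx, dy, dz).
#' @export
unique_offsets_3d <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), ]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(off, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  unname(off[keep, , drop = FALSE])
}

# index voxels of a 3D array shifted by offset o; returns matching index pairs
# (linear indices) for voxel pairs (v, v + o) both inside the lattice
shift_pairs <- function(dims, o) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  rng <- function(lo, hi) if (lo > hi) integer(0) else lo:hi
  xr <- rng(max(1, 1 - o[1]), min(nx, nx - o[1]))
  yr <- rng(max(1, 1 - o[2]), min(ny, ny - o[2]))
  zr <- rng(max(1, 1 - o[3]), min(nz, nz - o[3]))
  if (!length(xr) || !length(yr) || !length(zr))
    return(cbind(integer(0), integer(0)))
  ix <- as.vector(outer(outer(xr, (yr - 1) * nx, "+"), (zr - 1) * nx * ny, "+"))
  jx <- ix + o[1] + o[2] * nx + o[3] * nx * ny
  cbind(ix, jx)
}

#' Gray-level co-occurrence matrices (GLCM), one per direction
#'
#' Counts pairs of in-mask voxels at each of the 13 distance-1 offsets,
#' symmetrized (each pair counted in both orders) and normalized to sum to 1
#' per direction.
#'
#' @param disc A `discretized_roi`.
#' @return List with \code{p}: list of 13 normalized ng x ng matrices,
#'   \code{levels}: the gray-level values present, \code{offsets}.
#' @export
glcm_matrices <- function(disc) {
  lev <- disc$levels
  dims <- dim(lev)
  present <- sort(unique(lev[disc$mask]))
  ng <- length(present)
  ranks <- match(seq_len(max(present)), present)  # level value -> row index
  offs <- unique_offsets_3d()
  p <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    pr <- shift_pairs(dims, offs[k, ])
    li <- lev[pr[, 1]]; lj <- lev[pr[, 2]]
    ok <- !is.na(li) & !is.na(lj)
    m <- matrix(0, ng, ng)
    if (any(ok)) {
      ri <- ranks[li[ok]]; rj <- ranks[lj[ok]]
      cnt <- tabulate(ri + (rj - 1L) * ng, nbins = ng * ng)
      m <- matrix(cnt, ng, ng)
      m <- m + t(m)                       # symmetrize
      if (sum(m) > 0) m <- m / sum(m)
    }
    p[[k]] <- m
  }
  list(p = p, levels = present, offsets = offs)
}

#' Gray-level run-length matrices (GLRLM), one per direction
#'
#' A run is a maximal set of consecutive in-mask voxels of equal gray level
#' along a direction. Counts are accumulated into level x run-length matrices
#' for each of the 13 directions.
#'
#' @param disc A `discretized_roi`.
#' @return List with \code{p}: list of 13 ng x max-run-length count matrices,
#'   \code{levels}, \code{offsets}, \code{n_voxels}.
#' @export
glrlm_matrices <- function(disc) {
  lev <- disc$levels
  dims <- dim(lev)
  present <- sort(unique(lev[disc$mask]))
  ng <- length(present)
  ranks <- match(seq_len(max(present)), present)
  offs <- unique_offsets_3d()
  nvox <- sum(disc$mask)
  idx <- which(disc$mask)
  co <- arrayInd(idx, dims)
  out <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    # step index t increments by 1 along the ray: use the coordinate on the
    # first nonzero axis of o (times its sign); co - t*o is constant per line
    ax <- which(o != 0)[1]
    tpos <- co[, ax] * o[ax]
    base <- co - outer(tpos, o)
    key <- paste(base[, 1], base[, 2], base[, 3], sep = ",")
    ord <- order(key, tpos)
    kk <- key[ord]; tt <- tpos[ord]; ll <- lev[idx][ord]
    # run breaks: new line, gap in position, or level change
    n <- length(ord)
    if (n == 0) { out[[k]] <- matrix(0, ng, 1); next }
    brk <- c(TRUE, kk[-1] != kk[-n] | tt[-1] != tt[-n] + 1L |
               ll[-1] != ll[-n])
    run_id <- cumsum(brk)
    run_len <- tabulate(run_id)
    run_lev <- ll[brk]
    maxlen <- max(run_len)
    m <- matrix(0, ng, maxlen)
    for (r in seq_along(run_len)) {
      ri <- ranks[run_lev[r]]
      m[ri, run_len[r]] <- m[ri, run_len[r]] + 1
    }
    out[[k]] <- m
  }
  list(p = out, levels = present, offsets = offs, n_voxels = nvox)
}

# label 26-connected components of in-mask voxels sharing a gray level
# returns integer zone labels (1..n_zones) per in-mask voxel, in which(mask)
# order; union-find with path halving over the equal-level neighbor graph
connected_zones <- function(disc) {
  dims <- dim(disc$levels)
  idx <- which(disc$mask)
  n <- length(idx)
  parent <- seq_len(n)
  pos <- array(0L, dims); pos[idx] <- seq_len(n)
  lev <- disc$levels
  offs <- unique_offsets_3d()
  ea <- integer(0); eb <- integer(0)
  for (k in seq_len(nrow(offs))) {
    pr <- shift_pairs(dims, offs[k, ])
    a <- pos[pr[, 1]]; b <- pos[pr[, 2]]
    ok <- a > 0L & b > 0L & lev[pr[, 1]] == lev[pr[, 2]]
    ok[is.na(ok)] <- FALSE
    ea <- c(ea, a[ok]); eb <- c(eb, b[ok])
  }
  # vectorized pointer-jumping union-find over the edge list
  if (length(ea)) {
    repeat {
      repeat {  # full path compression
        pp <- parent[parent]
        if (identical(pp, parent)) break
        parent <- pp
      }
      ra <- parent[ea]; rb <- parent[eb]
      lo <- pmin(ra, rb); hi <- pmax(ra, rb)
      diff <- hi != lo
      if (!any(diff)) break
      lo <- lo[diff]; hi <- hi[diff]
      o <- order(hi, lo)
      hi <- hi[o]; lo <- lo[o]
      first <- !duplicated(hi)          # min lo per hi after the sort
      parent[hi[first]] <- pmin(parent[hi[first]], lo[first])
    }
  }
  match(parent, sort(unique(parent)))
}

#' Gray-level size-zone matrix (GLSZM)
#'
#' Zones are 26-connected components of equal-gray-level in-mask voxels; the
#' matrix counts zones by (gray level, zone size). Single matrix (no
#' directionality).
#'
#' @param disc A `discretized_roi`.
#' @return List with \code{p}: ng x max-zone-size count matrix, \code{levels},
#'   \code{n_voxels}.
#' @export
glszm_matrix <- function(disc) {
  idx <- which(disc$mask)
  present <- sort(unique(disc$levels[idx]))
  ng <- length(present)
  ranks <- match(seq_len(max(present)), present)
  zl <- connected_zones(disc)
  sizes <- tabulate(zl)
  first <- match(seq_along(sizes), zl)     # first voxel of each zone
  zone_lev <- disc$levels[idx][first]
  m <- matrix(0, ng, max(sizes))
  for (z in seq_along(sizes)) {
    ri <- ranks[zone_lev[z]]
    m[ri, sizes[z]] <- m[ri, sizes[z]] + 1
  }
  list(p = m, levels = present, n_voxels = length(idx))
}

#' Gray-level dependence matrix (GLDM)
#'
#' For each in-mask voxel, the dependence is 1 + the number of its in-mask
#' 26-neighbors whose gray level differs by at most \code{alpha} (default 0);
#' the center voxel counts as dependent on itself, so dependence >= 1. The
#' matrix counts voxels by (gray level, dependence).
#'
#' @param disc A `discretized_roi`.
#' @param alpha Gray-level tolerance (default 0).
#' @return List with \code{p}: ng x max-dependence count matrix, \code{levels},
#'   \code{n_voxels}.
#' @export
gldm_matrix <- function(disc, alpha = 0) {
  dims <- dim(disc$levels)
  idx <- which(disc$mask)
  present <- sort(unique(disc$levels[idx]))
  ng <- length(present)
  ranks <- match(seq_len(max(present)), present)
  lev <- disc$levels
  dep <- integer(length(idx))
  pos <- array(0L, dims); pos[idx] <- seq_along(idx)
  offs <- unique_offsets_3d()
  for (k in seq_len(nrow(offs))) {
    pr <- shift_pairs(dims, offs[k, ])
    a <- pos[pr[, 1]]; b <- pos[pr[, 2]]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    depok <- abs(lev[idx[a]] - lev[idx[b]]) <= alpha
    if (any(depok)) {
      ta <- tabulate(a[depok], nbins = length(idx))
      tb <- tabulate(b[depok], nbins = length(idx))
      dep <- dep + ta + tb
    }
  }
  dep <- dep + 1L  # center voxel
  m <- matrix(0, ng, max(dep))
  for (v in seq_along(idx)) {
    ri <- ranks[lev[idx[v]]]
    m[ri, dep[v]] <- m[ri, dep[v]] + 1
  }
  list(p = m, levels = present, n_voxels = length(idx))
}

#' Neighborhood gray-tone difference matrix (NGTDM)
#'
#' For each in-mask voxel with at least one in-mask 26-neighbor, the absolute
#' difference between its gray level and the mean level of those neighbors is
#' accumulated per gray level.
#'
#' @param disc A `discretized_roi`.
#' @return List with \code{levels} (values present among counted voxels),
#'   \code{n_i} (voxel counts), \code{p_i} (probabilities), \code{s_i}
#'   (summed absolute differences), \code{n_vp} (total counted voxels).
#' @export
ngtdm_matrix <- function(disc) {
  dims <- dim(disc$levels)
  idx <- which(disc$mask)
  lev <- disc$levels
  pos <- array(0L, dims); pos[idx] <- seq_along(idx)
  nsum <- numeric(length(idx))
  ncnt <- integer(length(idx))
  offs <- unique_offsets_3d()
  for (k in seq_len(nrow(offs))) {
    pr <- shift_pairs(dims, offs[k, ])
    a <- pos[pr[, 1]]; b <- pos[pr[, 2]]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    la <- lev[idx[a]]; lb <- lev[idx[b]]
    nsum <- nsum + tabulate2(a, lb, length(idx)) + tabulate2(b, la, length(idx))
    ncnt <- ncnt + tabulate(a, nbins = length(idx)) +
      tabulate(b, nbins = length(idx))
  }
  has_nb <- ncnt > 0L
  x <- lev[idx][has_nb]
  diffs <- abs(x - nsum[has_nb] / ncnt[has_nb])
  present <- sort(unique(x))
  ri <- match(x, present)
  n_i <- tabulate(ri, nbins = length(present))
  s_i <- as.numeric(tapply(diffs, factor(ri, levels = seq_along(present)), sum))
  s_i[is.na(s_i)] <- 0
  n_vp <- sum(n_i)
  list(levels = present, n_i = n_i, p_i = n_i / n_vp, s_i = s_i, n_vp = n_vp)
}

# weighted tabulate: sum w over bins given by index vector
tabulate2 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(as.numeric(w), bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Build all texture matrices for a discretized ROI
#'
#' @param disc A `discretized_roi`.
#' @return List with components \code{glcm}, \code{glrlm}, \code{glszm},
#'   \code{gldm}, \code{ngtdm} (see the individual builders).
#' @export
build_matrices <- function(disc) {
  list(glcm = glcm_matrices(disc),
       glrlm = glrlm_matrices(disc),
       glszm = glszm_matrix(disc),
       gldm = gldm_matrix(disc),
       ngtdm = ngtdm_matrix(disc))
}
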