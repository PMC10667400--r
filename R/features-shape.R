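# 3D shape features from the binary mask and voxel spacing.
#
# The surface mesh is a marching-tetrahedra triangulation of the 0.5
# iso-level of the zero-padded binary mask in physical (mm) coordinates:
# each lattice cube is split into 6 tetrahedra and every tetrahedron with
# mixed inside/outside corners contributes 1 or 2 triangles with vertices at
# edge midpoints. The mesh is closed and consistently oriented (normals
# outward), so MeshVolume is the exact volume of the enclosed polyhedron via
# the divergence theorem and SurfaceArea the exact area of its boundary.

# 6-tetrahedra decomposition of the unit cube (corner indices 1..8 of a cube
# with corner k at offsets bit pattern: 1=(0,0,0), 2=(1,0,0), 3=(0,1,0),
# 4=(1,1,0), 5=(0,0,1), 6=(1,0,1), 7=(0,1,1), 8=(1,1,1)); all share the
# main diagonal 1-8
tet_decomposition <- function() {
  matrix(c(1, 2, 4, 8,
           1, 4, 3, 8,
           1, 3, 7, 8,
           1, 7, 5, 8,
           1, 5, 6, 8,
           1, 6, 2, 8), ncol = 4, byrow = TRUE)
}

cube_corner_offsets <- function() {
  matrix(c(0, 0, 0,  1, 0, 0,  0, 1, 0,  1, 1, 0,
           0, 0, 1,  1, 0, 1,  0, 1, 1,  1, 1, 1), ncol = 3, byrow = TRUE)
}

#' Marching-tetrahedra surface mesh of a binary mask
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm (length 3).
#' @return List with \code{vertices} (V x 3 matrix, mm, voxel centers at
#'   (index - 1) * spacing) and \code{triangles} (T x 3 index matrix into
#'   vertices, oriented with outward normals).
#' @export
mask_mesh <- function(mask, spacing) {
  dims <- dim(mask)
  pad <- array(FALSE, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  pd <- dim(pad)
  f <- array(0, pd); f[pad] <- 1
  # cubes with mixed corners only
  idx <- which(pad)
  co <- arrayInd(idx, pd)
  # candidate cube origins: neighborhood of inside voxels
  origins <- unique(do.call(rbind, lapply(list(c(0, 0, 0), c(-1, 0, 0),
    c(0, -1, 0), c(0, 0, -1), c(-1, -1, 0), c(-1, 0, -1), c(0, -1, -1),
    c(-1, -1, -1)), function(o) sweep(co, 2, -o))))
  keep <- origins[, 1] >= 1 & origins[, 2] >= 1 & origins[, 3] >= 1 &
    origins[, 1] < pd[1] & origins[, 2] < pd[2] & origins[, 3] < pd[3]
  origins <- origins[keep, , drop = FALSE]
  corner_off <- cube_corner_offsets()
  lin <- function(x, y, z) x + (y - 1) * pd[1] + (z - 1) * pd[1] * pd[2]
  corner_idx <- sapply(seq_len(8), function(k)
    lin(origins[, 1] + corner_off[k, 1], origins[, 2] + corner_off[k, 2],
        origins[, 3] + corner_off[k, 3]))
  if (is.null(dim(corner_idx)))
    corner_idx <- matrix(corner_idx, ncol = 8)
  inside <- matrix(pad[corner_idx], ncol = 8)
  mixed <- rowSums(inside) > 0 & rowSums(inside) < 8
  origins <- origins[mixed, , drop = FALSE]
  inside <- inside[mixed, , drop = FALSE]
  if (!nrow(origins))
    return(list(vertices = matrix(0, 0, 3), triangles = matrix(0L, 0, 3)))
  tets <- tet_decomposition()
  tri_list <- list()
  # physical coordinates of cube corners: (grid index - 2) * spacing so that
  # original-volume voxel i sits at (i - 1) * spacing
  corner_phys <- lapply(seq_len(8), function(k)
    sweep(sweep(origins, 2, corner_off[k, ] - 2, "+"), 2, spacing, "*"))
  for (t in seq_len(6)) {
    vids <- tets[t, ]
    ins <- inside[, vids, drop = FALSE]
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    act <- which(code > 0L & code < 15L)
    if (!length(act)) next
    P <- lapply(seq_len(4), function(k) corner_phys[[vids[k]]][act, , drop = FALSE])
    cd <- code[act]
    tri_list[[length(tri_list) + 1L]] <- mt_triangles(P, cd)
  }
  if (!length(tri_list))
    return(list(vertices = matrix(0, 0, 3), triangles = matrix(0L, 0, 3)))
  tris <- do.call(rbind, tri_list)   # each row: 9 numbers (3 vertices)
  # deduplicate vertices
  verts <- rbind(tris[, 1:3], tris[, 4:6], tris[, 7:9])
  key <- paste(round(verts[, 1], 9), round(verts[, 2], 9),
               round(verts[, 3], 9))
  uk <- !duplicated(key)
  vmap <- match(key, key[uk])
  V <- verts[uk, , drop = FALSE]
  n <- nrow(tris)
  Tm <- cbind(vmap[seq_len(n)], vmap[n + seq_len(n)], vmap[2L * n + seq_len(n)])
  list(vertices = V, triangles = Tm)
}

# triangles for marching tetrahedra; P: list of 4 (n x 3) corner coordinate
# matrices; code: per-row 4-bit inside pattern (bit k = corner k inside).
# Vertices at edge midpoints; triangles oriented with outward normals
# (away from the inside corners). Returns n_tri x 9 matrix.
mt_triangles <- function(P, code) {
  mid <- function(A, B) (A + B) / 2
  out <- list()
  emit <- function(a, b, c, inside_pt) {
    # orient so normal points away from the inside reference point
    n1 <- vcross(b - a, c - a)
    d <- rowSums(n1 * (a - inside_pt))
    flip <- d < 0
    b2 <- b; c2 <- c
    b2[flip, ] <- c[flip, , drop = FALSE]
    c2[flip, ] <- b[flip, , drop = FALSE]
    out[[length(out) + 1L]] <<- cbind(a, b2, c2)
  }
  for (cd in unique(code)) {
    rows <- which(code == cd)
    ins <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0L)
    outs <- setdiff(1:4, ins)
    Pr <- lapply(P, function(M) M[rows, , drop = FALSE])
    if (length(ins) == 1L) {
      i <- ins
      m <- lapply(outs, function(o) mid(Pr[[i]], Pr[[o]]))
      emit(m[[1]], m[[2]], m[[3]], Pr[[i]])
    } else if (length(ins) == 3L) {
      o <- outs
      m <- lapply(ins, function(i) mid(Pr[[i]], Pr[[o]]))
      ref <- (Pr[[ins[1]]] + Pr[[ins[2]]] + Pr[[ins[3]]]) / 3
      emit(m[[1]], m[[2]], m[[3]], ref)
    } else { # 2 inside, 2 outside -> quad split into 2 triangles
      i1 <- ins[1]; i2 <- ins[2]; o1 <- outs[1]; o2 <- outs[2]
      a <- mid(Pr[[i1]], Pr[[o1]])
      b <- mid(Pr[[i1]], Pr[[o2]])
      cc <- mid(Pr[[i2]], Pr[[o2]])
      d <- mid(Pr[[i2]], Pr[[o1]])
      ref <- (Pr[[i1]] + Pr[[i2]]) / 2
      emit(a, b, cc, ref)
      emit(a, cc, d, ref)
    }
  }
  do.call(rbind, out)
}

vcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

mesh_volume_area <- function(mesh) {
  if (!nrow(mesh$triangles)) return(c(volume = 0, area = 0))
  A <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  B <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  C <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  cr <- vcross(B - A, C - A)
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- sum(rowSums(A * vcross(B, C))) / 6
  c(volume = abs(vol), area = area)
}

# maximum pairwise distance among points (exact, chunked to bound memory)
max_pairwise_dist <- function(P) {
  P <- unique(P)
  n <- nrow(P)
  if (n < 2) return(0)
  sq <- rowSums(P^2)
  best <- 0
  chunk <- 512L
  for (i0 in seq(1L, n, by = chunk)) {
    ii <- i0:min(n, i0 + chunk - 1L)
    D <- outer(sq[ii], sq, "+") - 2 * P[ii, , drop = FALSE] %*% t(P)
    best <- max(best, max(D))
  }
  sqrt(max(best, 0))
}

#' 3D shape features (14)
#'
#' VoxelVolume counts voxels times the voxel volume; MeshVolume and
#' SurfaceArea come from the closed surface mesh; Sphericity =
#' (36 pi V^2)^(1/3) / A with mesh volume and area; Maximum3DDiameter and
#' the three Maximum2DDiameter features are maximal pairwise distances among
#' surface vertices in 3D and in the three axis-dropping projections
#' (Slice drops the 3rd axis, Column drops the 2nd, Row drops the 1st).
#' Axis lengths are 4 * sqrt(eigenvalue) of the physical-coordinate
#' covariance (n - 1 denominator) of in-mask voxel centers; Elongation and
#' Flatness are square roots of eigenvalue ratios. Degenerate single-voxel
#' masks give zero axis lengths and zero Elongation/Flatness.
#'
#' @param mask Logical 3D array (nonempty).
#' @param spacing Voxel spacing in mm (length 3).
#' @return Named numeric vector of 14 values, names prefixed "Shape_".
#' @export
shape_features <- function(mask, spacing) {
  if (!any(mask)) stop("mask is empty")
  nvox <- sum(mask)
  vv <- prod(spacing)
  mesh <- mask_mesh(mask, spacing)
  va <- mesh_volume_area(mesh)
  V <- va["volume"]; A <- va["area"]
  sph <- if (A > 0) (36 * pi * V^2)^(1 / 3) / A else 0
  Vx <- mesh$vertices
  d3 <- max_pairwise_dist(Vx)
  d_slice <- max_pairwise_dist(Vx[, c(1, 2), drop = FALSE])
  d_col <- max_pairwise_dist(Vx[, c(1, 3), drop = FALSE])
  d_row <- max_pairwise_dist(Vx[, c(2, 3), drop = FALSE])
  co <- arrayInd(which(mask), dim(mask))
  phys <- sweep(sweep(co, 2, 1), 2, spacing, "*")
  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  out <- c(
    MeshVolume = unname(V),
    VoxelVolume = nvox * vv,
    SurfaceArea = unname(A),
    SurfaceVolumeRatio = unname(if (V > 0) A / V else 0),
    Sphericity = unname(sph),
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d_slice,
    Maximum2DDiameterColumn = d_col,
    Maximum2DDiameterRow = d_row,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    LeastAxisLength = least,
    Elongation = elong,
    Flatness = flat
  )
  names(out) <- paste0("Shape_", names(out))
  out
}
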