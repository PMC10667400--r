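#' Simulation configuration for a paired test-retest cohort
#'
#' The simulator stands in for a prostate T2-weighted test-retest dataset:
#' each lesion is an ellipsoidal ROI embedded in a small per-lesion grid with
#' anisotropic voxels, imaged "twice". Scan 2 receives an arbitrary-unit
#' gain/offset drift (T2-weighted intensities have no absolute scale), and
#' each scan has its own slightly-jittered delineation. The in-lesion signal
#' decomposes into a latent texture field shared by both scans (amplitude
#' variance \code{var_shared}) plus a scan-specific field (amplitude variance
#' \code{var_independent}), so the ratio
#' var_shared / (var_shared + var_independent) is a known reliability anchor.
#'
#' @param n_patients Number of patients (default 50).
#' @param total_lesions Total lesion count; extra (non-index) lesions are
#'   spread randomly over patients, at most 3 lesions each (default 74).
#' @param grid_shape Voxels per axis of each per-lesion grid.
#' @param voxel_spacing mm, default c(0.5, 0.5, 3).
#' @param var_shared Variance of the shared (between-lesion) texture
#'   amplitude, sigma_a^2.
#' @param var_independent Variance of the scan-specific amplitude, sigma_e^2.
#' @param noise_sd SD of additive voxel noise (arbitrary units).
#' @param scale_drift List with \code{gain} and \code{offset} ranges applied
#'   to scan 2.
#' @param lesion_radius_range In-plane lesion semi-axis range in mm.
#' @param reference_levels Mean intensities c(fat, muscle) of the reference
#'   boxes (arbitrary units).
#' @param base_level Mean lesion-bed intensity (arbitrary units).
#' @param texture_amplitude Intensity scale of the texture fields.
#' @param smoothing_vox Gaussian-smoothing sigmas (voxels) per axis for the
#'   latent fields.
#' @param mask_jitter_prob Probability that a boundary voxel of the ellipsoid
#'   is flipped in a given scan's delineation (0 disables jitter).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 50L, total_lesions = 74L,
                       grid_shape = c(56L, 56L, 16L),
                       voxel_spacing = c(0.5, 0.5, 3.0),
                       var_shared = 1, var_independent = 1,
                       noise_sd = 10,
                       scale_drift = list(gain = c(0.8, 1.25),
                                          offset = c(-50, 50)),
                       lesion_radius_range = c(4, 12),
                       reference_levels = c(fat = 800, muscle = 200),
                       base_level = 400,
                       texture_amplitude = 80,
                       smoothing_vox = c(2, 2, 0.5),
                       mask_jitter_prob = 0.15,
                       seed = 1L) {
  stopifnot(var_shared >= 0, var_independent >= 0, noise_sd >= 0,
            n_patients >= 1, total_lesions >= n_patients,
            total_lesions <= 3L * n_patients,
            length(grid_shape) == 3, length(voxel_spacing) == 3,
            all(voxel_spacing > 0))
  cfg <- list(n_patients = as.integer(n_patients),
              total_lesions = as.integer(total_lesions),
              grid_shape = as.integer(grid_shape),
              voxel_spacing = voxel_spacing,
              var_shared = var_shared, var_independent = var_independent,
              noise_sd = noise_sd, scale_drift = scale_drift,
              lesion_radius_range = lesion_radius_range,
              reference_levels = reference_levels,
              base_level = base_level,
              texture_amplitude = texture_amplitude,
              smoothing_vox = smoothing_vox,
              mask_jitter_prob = mask_jitter_prob,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Analytic reliability anchor of a configuration
#'
#' Returns var_shared / (var_shared + var_independent): the true ICC of any
#' statistic linear in the latent amplitudes when voxel noise, drift and mask
#' jitter are switched off.
#'
#' @param config A `sim_config`.
#' @return Fraction in \[0, 1\].
#' @export
expected_reliability <- function(config) {
  tot <- config$var_shared + config$var_independent
  if (tot <= 0) stop("undefined reliability: var_shared + var_independent = 0")
  config$var_shared / tot
}

# separable Gaussian smoothing of a 3D array (kernel truncated at 3 sigma);
# sigma of 0 on an axis disables smoothing there
smooth3d <- function(x, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    x <- apply_conv_axis(x, k, ax)
  }
  x
}

apply_conv_axis <- function(x, k, ax) {
  d <- dim(x)
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  r <- (length(k) - 1L) / 2L
  # reflect-pad along the filtered axis
  padm <- rbind(m[rev(seq_len(r)), , drop = FALSE], m,
                m[nrow(m) - seq_len(r) + 1L, , drop = FALSE])
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (i in seq_along(k))
    out <- out + k[i] * padm[(i - 1L) + seq_len(dp[1]), , drop = FALSE]
  xp <- array(out, dp)
  aperm(xp, order(perm))
}

# ellipsoid mask centered in the grid with semi-axes in mm
ellipsoid_mask <- function(grid_shape, spacing, semi_axes_mm) {
  ctr <- (grid_shape - 1) / 2
  co <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  u <- sweep(sweep(co, 2, ctr + 1), 2, spacing, "*")
  v <- sweep(u, 2, semi_axes_mm, "/")
  array(rowSums(v^2) <= 1, grid_shape)
}

# flip a random subset of boundary voxels (26-neighborhood boundary)
jitter_mask <- function(mask, prob) {
  if (prob <= 0) return(mask)
  dims <- dim(mask)
  offs <- unique_offsets_3d()
  inner_boundary <- mask & !erode_once(mask, offs, dims)
  outer_boundary <- !mask & dilate_once(mask, offs, dims)
  cand <- which(inner_boundary | outer_boundary)
  flip <- cand[stats::runif(length(cand)) < prob]
  out <- mask
  out[flip] <- !out[flip]
  # never let jitter empty the mask core
  if (!any(out)) out <- mask
  out
}

erode_once <- function(mask, offs, dims) {
  out <- mask
  for (k in seq_len(nrow(offs))) for (sgn in c(1, -1)) {
    pr <- shift_pairs(dims, sgn * offs[k, ])
    keep <- array(FALSE, dims)
    keep[pr[, 1]] <- mask[pr[, 2]]
    out <- out & keep
  }
  out
}

dilate_once <- function(mask, offs, dims) {
  out <- mask
  for (k in seq_len(nrow(offs))) for (sgn in c(1, -1)) {
    pr <- shift_pairs(dims, sgn * offs[k, ])
    add <- array(FALSE, dims)
    add[pr[, 1]] <- mask[pr[, 2]]
    out <- out | add
  }
  out
}

# clinical variables with the cohort's published marginals:
# PSAD ~ lognormal matched to mean 0.34, sd 0.30 ng/mL^2; prostate volume
# ~ lognormal matched to mean 46.94, sd 19.49 mL; PI-RADS sampled with
# probabilities 18/74, 30/74, 26/74 for scores 3/4/5; ISUP (index lesions)
# with probabilities 11/8/15/8/6/2 over <1 (coded 0) and grades 1..5
draw_clinical <- function(n_patients) {
  ln_pars <- function(m, s) {
    s2 <- log(1 + (s / m)^2)
    c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  pp <- ln_pars(0.34, 0.30)
  pv <- ln_pars(46.94, 19.49)
  list(psad = stats::rlnorm(n_patients, pp[1], pp[2]),
       volume = stats::rlnorm(n_patients, pv[1], pv[2]))
}

draw_pirads <- function(n) {
  sample(c(3L, 4L, 5L), n, replace = TRUE, prob = c(18, 30, 26) / 74)
}

draw_isup <- function(n) {
  sample(0:5, n, replace = TRUE, prob = c(11, 8, 15, 8, 6, 2) / 50)
}

#' Generate a paired test-retest cohort with known reliability structure
#'
#' Each lesion's in-mask signal is
#' gain_s * (base + a_l * T_l + e_ls * U_ls + noise) + offset_s,
#' where T_l is a smoothed Gaussian random field shared by both scans, U_ls
#' is an independent field per scan, a_l ~ N(0, var_shared) is the shared
#' amplitude and e_ls ~ N(0, var_independent) the scan-specific one; gain and
#' offset drift apply to scan 2 only. Masks are ellipsoids with independent
#' per-scan boundary jitter; fat and muscle reference boxes sit in grid
#' corners. Deterministic given the config (including its seed).
#'
#' @param config A `sim_config`.
#' @return List of `paired_lesion_case`; attribute \code{clinical} holds the
#'   per-lesion clinical table as a data.frame.
#' @export
generate_cohort <- function(config) {
  gs <- config$grid_shape
  sp <- config$voxel_spacing
  rmax <- config$lesion_radius_range[2]
  need <- ceiling(2 * rmax / sp) + 2
  for (ax in 1:3) {
    if (gs[ax] < need[ax])
      stop("grid_shape axis ", ax, " (", gs[ax], " voxels) cannot contain a ",
           rmax, " mm lesion radius at spacing ", sp[ax],
           " mm (needs >= ", need[ax], ")")
  }
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  npat <- config$n_patients
  extra <- config$total_lesions - npat
  extra_counts <- tabulate(sample(rep(seq_len(npat), 2L), extra), nbins = npat)
  lesions_per_patient <- 1L + extra_counts
  pat <- draw_clinical(npat)
  refs <- reference_masks(gs)
  cohort <- list()
  clin_rows <- list()
  lesion_no <- 0L
  for (p in seq_len(npat)) {
    for (l in seq_len(lesions_per_patient[p])) {
      lesion_no <- lesion_no + 1L
      lesion_id <- sprintf("L%03d", lesion_no)
      is_index <- l == 1L
      semi_xy <- stats::runif(2, config$lesion_radius_range[1],
                              config$lesion_radius_range[2])
      semi_z <- stats::runif(1, max(sp[3], config$lesion_radius_range[1]),
                             config$lesion_radius_range[2])
      base_mask <- ellipsoid_mask(gs, sp, c(semi_xy, semi_z))
      m1 <- jitter_mask(base_mask, config$mask_jitter_prob)
      m2 <- jitter_mask(base_mask, config$mask_jitter_prob)
      # keep masks clear of the reference boxes
      m1 <- m1 & !refs$fat & !refs$muscle
      m2 <- m2 & !refs$fat & !refs$muscle
      Tl <- unit_field(gs, config$smoothing_vox)
      U1 <- unit_field(gs, config$smoothing_vox)
      U2 <- unit_field(gs, config$smoothing_vox)
      a_l <- stats::rnorm(1, 0, sqrt(config$var_shared))
      e1 <- stats::rnorm(1, 0, sqrt(config$var_independent))
      e2 <- stats::rnorm(1, 0, sqrt(config$var_independent))
      amp <- config$texture_amplitude
      sig1 <- config$base_level + amp * (a_l * Tl + e1 * U1)
      sig2 <- config$base_level + amp * (a_l * Tl + e2 * U2)
      n1 <- if (config$noise_sd > 0)
        array(stats::rnorm(prod(gs), 0, config$noise_sd), gs) else 0
      n2 <- if (config$noise_sd > 0)
        array(stats::rnorm(prod(gs), 0, config$noise_sd), gs) else 0
      v1 <- sig1 + n1
      v2 <- sig2 + n2
      # reference tissue boxes carry their mean level plus noise
      for (s in c("fat", "muscle")) {
        lvl <- config$reference_levels[[s]]
        v1[refs[[s]]] <- lvl + stats::rnorm(sum(refs[[s]]), 0,
                                            max(config$noise_sd, 1e-12))
        v2[refs[[s]]] <- lvl + stats::rnorm(sum(refs[[s]]), 0,
                                            max(config$noise_sd, 1e-12))
      }
      gain <- stats::runif(1, config$scale_drift$gain[1],
                           config$scale_drift$gain[2])
      offset <- stats::runif(1, config$scale_drift$offset[1],
                             config$scale_drift$offset[2])
      v2 <- gain * v2 + offset
      clin <- list(psad = pat$psad[p], prostate_volume = pat$volume[p],
                   pirads = draw_pirads(1), isup = draw_isup(1),
                   is_index = is_index)
      case <- structure(list(
        lesion_id = lesion_id, patient_id = sprintf("P%03d", p),
        spacing = sp,
        scan1_volume = v1, scan2_volume = v2,
        scan1_mask = m1, scan2_mask = m2,
        fat_mask = refs$fat, muscle_mask = refs$muscle,
        clinical = clin), class = "paired_lesion_case")
      cohort[[lesion_no]] <- case
      clin_rows[[lesion_no]] <- data.frame(
        lesion_id = lesion_id, patient_id = sprintf("P%03d", p),
        psad = clin$psad, prostate_volume = clin$prostate_volume,
        pirads = clin$pirads, isup = clin$isup, is_index = clin$is_index,
        stringsAsFactors = FALSE)
    }
  }
  attr(cohort, "clinical") <- do.call(rbind, clin_rows)
  attr(cohort, "config") <- config
  cohort
}

# standard-normal smoothed field rescaled to unit voxel variance
unit_field <- function(gs, smoothing_vox) {
  f <- array(stats::rnorm(prod(gs)), gs)
  f <- smooth3d(f, smoothing_vox)
  f / stats::sd(f)
}

# fat and muscle reference boxes in opposite grid corners
reference_masks <- function(gs) {
  fat <- array(FALSE, gs)
  mus <- array(FALSE, gs)
  bx <- pmin(6L, gs[1]); by <- pmin(6L, gs[2]); bz <- pmin(3L, gs[3])
  fat[1:bx, 1:by, 1:bz] <- TRUE
  mus[(gs[1] - bx + 1):gs[1], (gs[2] - by + 1):gs[2], 1:bz] <- TRUE
  list(fat = fat, muscle = mus)
}

#' @export
print.paired_lesion_case <- function(x, ...) {
  cat(sprintf(
    "<paired_lesion_case> %s (%s%s) grid %s, %d/%d mask voxels\n",
    x$lesion_id, x$patient_id, if (x$clinical$is_index) ", index" else "",
    paste(dim(x$scan1_volume), collapse = "x"),
    sum(x$scan1_mask), sum(x$scan2_mask)))
  invisible(x)
}

#' Tabular fast path: paired feature table with known true ICC
#'
#' Each feature column pair follows the two-way random model
#' y_is = mu_f + r_i + e_is with between-subject variance \code{true_icc} and
#' residual variance 1 - \code{true_icc}, so the population ICC(2,1) equals
#' \code{true_icc}.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param true_icc True reliability in \[0, 1).
#' @param n_features Number of independent features.
#' @param seed Integer seed.
#' @return 3D array \[n_subjects, 2, n_features\] with dimnames on the
#'   feature axis.
#' @export
simulate_feature_table <- function(n_subjects, true_icc, n_features = 1L,
                                   seed = 1L) {
  if (true_icc < 0 || true_icc >= 1)
    stop("true_icc must be in [0, 1)")
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  out <- array(0, c(n_subjects, 2L, n_features),
               dimnames = list(NULL, c("scan1", "scan2"),
                               sprintf("F%03d", seq_len(n_features))))
  for (f in seq_len(n_features)) {
    r <- stats::rnorm(n_subjects, 0, sqrt(true_icc))
    e <- matrix(stats::rnorm(2L * n_subjects, 0, sqrt(1 - true_icc)),
                n_subjects, 2L)
    out[, , f] <- r + e
  }
  out
}
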