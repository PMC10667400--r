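#' Pre-processing settings grid
#'
#' The study design crosses three pre-processing parameters:
#' gray-level discretization (fixed bin number, FBN, with 16/32/64/128 bins,
#' or fixed bin size, FBS, with bin widths 5/10/20/40), signal-intensity
#' normalization (AR = dual-reference normalization applied, NAR = not
#' applied), and intensity outlier filtering (NoF = none, IN = clip to
#' \[mu - 3 sigma, mu + 3 sigma\], OUT = drop voxels outside that range from
#' the mask). The full Cartesian product gives 2 x 4 x 2 x 3 = 48 settings.
#'
#' @return A data.frame with one row per setting and columns
#'   \code{setting_index} (1..48, stable across runs), \code{discretization}
#'   ("FBN"/"FBS"), \code{binning} (bin number or bin width), \code{normalization}
#'   ("AR"/"NAR") and \code{outlier_mode} ("NoF"/"IN"/"OUT"). Ordering is
#'   discretization-major (FBN first), then binning ascending, then
#'   normalization ("AR" before "NAR"), then outlier mode (NoF, IN, OUT).
#' @examples
#' grid <- enumerate_settings()
#' nrow(grid)            # 48
#' grid[grid$setting_index == 18, ]
#' @export
enumerate_settings <- function() {
  disc <- c("FBN", "FBS")
  bins <- list(FBN = c(16L, 32L, 64L, 128L), FBS = c(5L, 10L, 20L, 40L))
  norm <- c("AR", "NAR")
  outl <- c("NoF", "IN", "OUT")
  rows <- list()
  for (d in disc) {
    for (b in bins[[d]]) {
      for (nm in norm) {
        for (om in outl) {
          rows[[length(rows) + 1L]] <- data.frame(
            discretization = d, binning = b, normalization = nm,
            outlier_mode = om, stringsAsFactors = FALSE)
        }
      }
    }
  }
  grid <- do.call(rbind, rows)
  grid <- cbind(setting_index = seq_len(nrow(grid)), grid)
  grid
}

#' Fetch one pre-processing setting by index
#'
#' @param setting_index Integer in 1..48.
#' @return A one-row data.frame (see [enumerate_settings()]).
#' @export
get_setting <- function(setting_index) {
  grid <- enumerate_settings()
  if (!setting_index %in% grid$setting_index)
    stop("setting_index must be in 1..", nrow(grid))
  grid[grid$setting_index == setting_index, , drop = FALSE]
}

#' Human-readable setting label, e.g. "FBN64/NAR/OUT"
#' @param setting One-row setting data.frame.
#' @return Character scalar.
#' @export
setting_label <- function(setting) {
  paste0(setting$discretization, setting$binning, "/",
         setting$normalization, "/", setting$outlier_mode)
}

#' Dual-reference signal-intensity normalization
#'
#' T2-weighted intensities are in arbitrary units; this maps them onto a
#' common scale by anchoring the mean intensity of a muscle reference region
#' to \code{anchors[1]} and the mean of a fat reference region to
#' \code{anchors[2]} with a single affine (hence order-preserving) transform
#' applied to every voxel. It is a simplified stand-in for automated
#' dual-reference normalization: reference regions are supplied as masks
#' rather than detected.
#'
#' @param volume 3D numeric array of intensities.
#' @param fat_mask,muscle_mask Logical/0-1 arrays of the same shape.
#' @param anchors Numeric length-2: target (muscle, fat) means.
#'   Default c(0, 1000).
#' @return Normalized 3D array.
#' @export
normalize_dual_reference <- function(volume, fat_mask, muscle_mask,
                                     anchors = c(0, 1000)) {
  fat_mask <- as_mask(fat_mask, dim(volume), "fat_mask")
  muscle_mask <- as_mask(muscle_mask, dim(volume), "muscle_mask")
  if (!any(fat_mask)) stop("missing reference: fat mask is empty")
  if (!any(muscle_mask)) stop("missing reference: muscle mask is empty")
  m_fat <- mean(volume[fat_mask])
  m_mus <- mean(volume[muscle_mask])
  if (isTRUE(all.equal(m_fat, m_mus)))
    stop("degenerate reference: fat and muscle mean intensities are equal (",
         format(m_fat), ")")
  a <- (anchors[2] - anchors[1]) / (m_fat - m_mus)
  b <- anchors[1] - a * m_mus
  out <- a * volume + b
  attr(out, "normalization") <- c(gain = a, offset = b)
  out
}

#' Intensity outlier filtering (range re-segmentation)
#'
#' Computes mu and sigma once over the in-mask voxels, then either leaves the
#' ROI untouched (\code{"NoF"}), clips in-mask intensities into
#' \[mu - 3 sigma, mu + 3 sigma\] (\code{"IN"}, mask unchanged), or removes
#' voxels outside that range from the mask (\code{"OUT"}). sigma is the sample
#' standard deviation (n - 1 denominator) by default.
#'
#' @param volume 3D numeric array.
#' @param mask Logical/0-1 array, same shape, nonempty.
#' @param mode One of "NoF", "IN", "OUT".
#' @param n_sigma Half-width of the retained range in sigma units (default 3).
#' @param sd_denominator "n-1" (sample, default) or "n" (population).
#' @return List with \code{volume} (filtered), \code{mask} (possibly shrunken),
#'   \code{mu}, \code{sigma}, \code{mode}, \code{n_affected}.
#' @export
filter_outliers <- function(volume, mask, mode = c("NoF", "IN", "OUT"),
                            n_sigma = 3, sd_denominator = c("n-1", "n")) {
  mode <- match.arg(mode)
  sd_denominator <- match.arg(sd_denominator)
  mask <- as_mask(mask, dim(volume), "mask")
  if (!any(mask)) stop("mask is empty")
  x <- volume[mask]
  mu <- mean(x)
  sigma <- if (sd_denominator == "n-1") stats::sd(x) else
    sqrt(mean((x - mu)^2))
  if (length(x) == 1L || is.na(sigma)) sigma <- 0
  res <- list(volume = volume, mask = mask, mu = mu, sigma = sigma,
              mode = mode, n_affected = 0L)
  if (mode == "NoF") return(res)
  if (sigma == 0) {
    warning("sigma = 0 in outlier filter; nothing outside range, no-op")
    return(res)
  }
  lo <- mu - n_sigma * sigma
  hi <- mu + n_sigma * sigma
  outside <- mask & (volume < lo | volume > hi)
  res$n_affected <- sum(outside)
  if (mode == "IN") {
    v <- volume
    v[mask & volume < lo] <- lo
    v[mask & volume > hi] <- hi
    res$volume <- v
  } else { # OUT
    m <- mask
    m[outside] <- FALSE
    res$mask <- m
  }
  res
}

#' Fixed-bin-number (relative) gray-level discretization
#'
#' Maps in-mask intensities to integer levels 1..n_bins via
#' level(x) = floor(n_bins * (x - min) / (max - min)) + 1, with the maximum
#' clamped into the top bin. Invariant under positive affine intensity
#' transforms, which is the mechanism by which FBN absorbs arbitrary-unit
#' scanner drift. A constant ROI maps to a single level 1.
#'
#' @param volume 3D numeric array.
#' @param mask Logical/0-1 array, same shape, nonempty.
#' @param n_bins Number of gray levels (>= 2).
#' @return A `discretized_roi`: list with \code{levels} (integer array, NA
#'   outside mask), \code{mask}, \code{ng} (number of gray levels),
#'   \code{x_min}, \code{x_max}, \code{method}, \code{binning}.
#' @export
discretize_fbn <- function(volume, mask, n_bins) {
  mask <- as_mask(mask, dim(volume), "mask")
  if (!any(mask)) stop("mask is empty")
  if (n_bins < 2) stop("n_bins must be >= 2")
  x <- volume[mask]
  xmin <- min(x); xmax <- max(x)
  lev <- array(NA_integer_, dim(volume))
  if (xmax == xmin) {
    lev[mask] <- 1L
    ng <- 1L
  } else {
    l <- floor(n_bins * (x - xmin) / (xmax - xmin)) + 1
    l[l > n_bins] <- n_bins
    lev[mask] <- as.integer(l)
    ng <- as.integer(n_bins)
  }
  new_discretized_roi(lev, mask, ng, xmin, xmax, "FBN", n_bins)
}

#' Fixed-bin-size (absolute) gray-level discretization
#'
#' Bin edges are anchored at integer multiples of the bin width at or below
#' the in-mask minimum (the reference-tool convention), or at the ROI minimum
#' itself when \code{anchor = "roi_minimum"}. level(x) =
#' floor((x - lowest_edge) / width) + 1 with half-open bins, so a value
#' falling exactly on an edge joins the bin above.
#' Not scale invariant: doubling intensities roughly doubles the level count,
#' which is why absolute discretization is sensitive to scanner drift.
#'
#' @param volume 3D numeric array.
#' @param mask Logical/0-1 array, same shape, nonempty.
#' @param bin_width Positive bin width in intensity units.
#' @param anchor "multiple_of_width" (default) or "roi_minimum".
#' @return A `discretized_roi` (see [discretize_fbn()]).
#' @export
discretize_fbs <- function(volume, mask, bin_width,
                           anchor = c("multiple_of_width", "roi_minimum")) {
  anchor <- match.arg(anchor)
  mask <- as_mask(mask, dim(volume), "mask")
  if (!any(mask)) stop("mask is empty")
  if (bin_width <= 0) stop("bin_width must be > 0")
  x <- volume[mask]
  xmin <- min(x); xmax <- max(x)
  edge0 <- if (anchor == "multiple_of_width")
    bin_width * floor(xmin / bin_width) else xmin
  # half-open bins [edge, edge + width); a value on an edge joins the bin above
  l <- floor((x - edge0) / bin_width) + 1
  ng <- max(l)
  lev <- array(NA_integer_, dim(volume))
  lev[mask] <- as.integer(l)
  new_discretized_roi(lev, mask, as.integer(ng), xmin, xmax, "FBS", bin_width)
}

new_discretized_roi <- function(levels, mask, ng, x_min, x_max, method, binning) {
  structure(list(levels = levels, mask = mask, ng = ng,
                 x_min = x_min, x_max = x_max,
                 method = method, binning = binning),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi> %s binning=%g ng=%d voxels=%d range=[%g, %g]\n",
              x$method, x$binning, x$ng, sum(x$mask), x$x_min, x$x_max))
  invisible(x)
}

#' Apply one pre-processing setting to one scan of a lesion case
#'
#' Pipeline order: (1) dual-reference normalization if the setting is AR,
#' (2) intensity outlier filtering of the (possibly normalized) volume,
#' (3) gray-level discretization of the filtered ROI. First-order intensity
#' features use the continuous filtered volume and final mask; texture
#' features use the discretized ROI.
#'
#' @param case A `paired_lesion_case` (see [generate_cohort()]).
#' @param scan 1 or 2.
#' @param setting One-row setting data.frame (see [enumerate_settings()]).
#' @param anchors Normalization anchors, (muscle, fat) targets.
#' @return List with \code{volume} (filtered continuous), \code{mask} (final),
#'   \code{disc} (`discretized_roi`), \code{setting}.
#' @export
apply_setting <- function(case, scan, setting, anchors = c(0, 1000)) {
  stopifnot(scan %in% c(1, 2))
  vol <- if (scan == 1) case$scan1_volume else case$scan2_volume
  msk <- if (scan == 1) case$scan1_mask else case$scan2_mask
  if (setting$normalization == "AR") {
    vol <- normalize_dual_reference(vol, case$fat_mask, case$muscle_mask,
                                    anchors = anchors)
  }
  filt <- filter_outliers(vol, msk, mode = setting$outlier_mode)
  if (!any(filt$mask))
    stop("empty ROI after OUT filtering for lesion ", case$lesion_id,
         " under setting ", setting_label(setting))
  disc <- if (setting$discretization == "FBN")
    discretize_fbn(filt$volume, filt$mask, setting$binning)
  else
    discretize_fbs(filt$volume, filt$mask, setting$binning)
  list(volume = filt$volume, mask = filt$mask, disc = disc,
       spacing = case$spacing, setting = setting)
}

# coerce numeric/logical array to logical mask, validating shape and values
as_mask <- function(mask, dims, what = "mask") {
  if (is.null(dim(mask)) || !all(dim(mask) == dims))
    stop(what, " shape (", paste(dim(mask), collapse = "x"),
         ") does not match volume shape (", paste(dims, collapse = "x"), ")")
  if (is.logical(mask)) return(mask)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop(what, " is not binary: values ", paste(utils::head(setdiff(u, c(0, 1)), 3),
                                                collapse = ", "))
  array(mask != 0, dim = dims)
}
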