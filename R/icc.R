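#' Two-way random, single-measurement intra-class correlation ICC(2,1)
#'
#' Absolute-agreement reliability of one measurement per scan from the
#' two-way crossed ANOVA decomposition (rows = subjects, columns = scans):
#' ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE)).
#' All-identical tables give a zero denominator and are reported as ICC 1
#' with \code{degenerate = TRUE}.
#'
#' @param paired n x k numeric matrix (k = 2 scans in this study), no NA.
#' @return List of class `icc_result`: \code{icc}, \code{msr}, \code{msc},
#'   \code{mse}, \code{n}, \code{k}, \code{degenerate}.
#' @export
icc_2_1 <- function(paired) {
  paired <- as.matrix(paired)
  n <- nrow(paired); k <- ncol(paired)
  if (n < 3) stop("ICC needs at least 3 subjects, got ", n)
  if (anyNA(paired)) stop("missing cells in paired table")
  mu <- mean(paired)
  rm_ <- rowMeans(paired)
  cm <- colMeans(paired)
  ssr <- k * sum((rm_ - mu)^2)
  ssc <- n * sum((cm - mu)^2)
  sst <- sum((paired - mu)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  degenerate <- den <= .Machine$double.eps * max(1, abs(msr))
  icc <- if (degenerate) 1 else (msr - mse) / den
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse,
                 n = n, k = k, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f (n = %d, k = %d%s)\n", x$icc, x$n, x$k,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Reproducibility grid: ICC(2,1) of every feature under every setting
#'
#' @param features Long feature table from [extract_cohort()] (columns
#'   lesion_id, scan, setting_index, feature_name, value).
#' @param lesion_ids Optional subset of lesions (e.g., index lesions only).
#' @return List of class `repro_grid`: \code{icc} (feature x setting matrix),
#'   \code{degenerate} (logical matrix), \code{n} (subjects per cell),
#'   \code{settings}.
#' @export
build_grid <- function(features, lesion_ids = NULL) {
  if (!is.null(lesion_ids))
    features <- features[features$lesion_id %in% lesion_ids, , drop = FALSE]
  fnames <- sort(unique(features$feature_name))
  sidx <- sort(unique(features$setting_index))
  icc <- matrix(NA_real_, length(fnames), length(sidx),
                dimnames = list(fnames, as.character(sidx)))
  degen <- matrix(FALSE, length(fnames), length(sidx),
                  dimnames = dimnames(icc))
  ncell <- matrix(0L, length(fnames), length(sidx), dimnames = dimnames(icc))
  for (sj in seq_along(sidx)) {
    sub <- features[features$setting_index == sidx[sj], , drop = FALSE]
    wide1 <- sub[sub$scan == 1, c("lesion_id", "feature_name", "value")]
    wide2 <- sub[sub$scan == 2, c("lesion_id", "feature_name", "value")]
    lesions <- intersect(unique(wide1$lesion_id), unique(wide2$lesion_id))
    only <- union(setdiff(unique(wide1$lesion_id), lesions),
                  setdiff(unique(wide2$lesion_id), lesions))
    if (length(only))
      stop("unpaired lesion(s) under setting ", sidx[sj], ": ",
           paste(only, collapse = ", "))
    m1 <- matrix(NA_real_, length(lesions), length(fnames),
                 dimnames = list(lesions, fnames))
    m2 <- m1
    m1[cbind(match(wide1$lesion_id, lesions),
             match(wide1$feature_name, fnames))] <- wide1$value
    m2[cbind(match(wide2$lesion_id, lesions),
             match(wide2$feature_name, fnames))] <- wide2$value
    for (fi in seq_along(fnames)) {
      r <- icc_2_1(cbind(m1[, fi], m2[, fi]))
      icc[fi, sj] <- r$icc
      degen[fi, sj] <- r$degenerate
      ncell[fi, sj] <- r$n
    }
  }
  structure(list(icc = icc, degenerate = degen, n = ncell,
                 settings = sidx), class = "repro_grid")
}

#' Count features with good reproducibility per setting
#'
#' Strict inequality at the threshold; degenerate (all-identical) cells are
#' excluded from the count.
#'
#' @param grid A `repro_grid`.
#' @param threshold Good-reproducibility cutoff (default 0.75).
#' @return Named integer vector over settings.
#' @export
count_good <- function(grid, threshold = 0.75) {
  good <- grid$icc > threshold & !grid$degenerate
  counts <- colSums(good, na.rm = TRUE)
  stats::setNames(as.integer(counts), colnames(grid$icc))
}

#' Select the winning pre-processing setting
#'
#' Argmax of the good-feature count; ties are broken by the lowest binning
#' value among the tied settings. A residual tie (same binning value under
#' different discretizations or modes -- the published rule does not cover
#' this) is broken by the lowest setting index with a warning.
#'
#' @param counts Named counts from [count_good()].
#' @param settings Setting grid (default [enumerate_settings()]).
#' @return One-row setting data.frame with attribute \code{count}.
#' @export
select_setting <- function(counts, settings = enumerate_settings()) {
  idx <- as.integer(names(counts))
  best <- idx[counts == max(counts)]
  if (length(best) > 1L) {
    binning <- settings$binning[match(best, settings$setting_index)]
    best <- best[binning == min(binning)]
    if (length(best) > 1L) {
      warning("tie-break by binning value is ambiguous (settings ",
              paste(best, collapse = ", "),
              "); resolved by lowest setting index")
      best <- min(best)
    }
  }
  sel <- settings[settings$setting_index == best, , drop = FALSE]
  attr(sel, "count") <- unname(counts[as.character(best)])
  sel
}

#' Features with good reproducibility in every setting
#'
#' @param grid A `repro_grid`.
#' @param threshold Cutoff (default 0.75).
#' @return Character vector of feature names.
#' @export
consistently_good <- function(grid, threshold = 0.75) {
  if (!length(grid$icc)) stop("empty reproducibility grid")
  good <- grid$icc > threshold & !grid$degenerate
  rownames(grid$icc)[rowSums(good, na.rm = TRUE) == ncol(grid$icc) &
                       !apply(is.na(grid$icc), 1, any)]
}
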