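#' Two-tailed Mann-Whitney U test
#'
#' Exact enumeration p-value for combined n <= 12 without ties; otherwise the
#' normal approximation with mid-ranks, tie correction and continuity
#' correction. (The switch mirrors the convention of standard implementations
#' and is reported in the result.)
#'
#' @param x,y Numeric samples (nonempty).
#' @return List: \code{U} (statistic for x), \code{p} (two-tailed),
#'   \code{method} ("exact" or "normal").
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (nx + ny <= 12 && !ties) {
    # exact two-sided p from the null distribution of U: double the smaller
    # tail (U is symmetric about nx * ny / 2)
    u <- round(U)
    lo <- stats::pwilcox(u, nx, ny)
    hi <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  nt <- nx + ny
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (nt * (nt - 1))
  sigma2 <- nx * ny / 12 * (nt + 1 - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal")
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with mid-ranks and tie correction; p-value from the
#' chi-squared distribution with (number of groups - 1) degrees of freedom.
#'
#' @param groups List of >= 2 nonempty numeric samples.
#' @return List: \code{H}, \code{p}, \code{df}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty group")
  x <- unlist(groups)
  n <- length(x)
  if (n < 5) warning("total n < 5: chi-squared approximation is poor")
  r <- rank(x)
  grp <- rep(seq_along(groups), sizes)
  rs <- tapply(r, grp, sum)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  tie_tab <- table(x)
  C <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (C > 0) H <- H / C
  df <- length(groups) - 1
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  list(H = H, p = p, df = df)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' adj_i = min over j >= i (in ascending order) of m * p_(j) / j, capped at
#' 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p))
    stop("p-values must be in [0, 1] and non-missing")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- m * p[o] / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# clinical category assignment per published cut-offs
category_of <- function(clinical, variable) {
  switch(variable,
    PSAD = ifelse(clinical$psad <= 0.15, "low", "high"),
    prostate_volume = ifelse(clinical$prostate_volume < 40,
                             "small", "enlarged"),
    PIRADS = as.character(clinical$pirads),
    ISUP = ifelse(clinical$isup < 1, "<1",
                  ifelse(clinical$isup == 1, "1", ">1")),
    stop("unknown clinical variable: ", variable))
}

clinical_variables <- function() c("PSAD", "prostate_volume", "PIRADS", "ISUP")

#' Compare feature reproducibility (ICC) across clinical categories
#'
#' For each clinical variable, lesions (index lesions only, by design) are
#' split into categories, the per-feature ICC(2,1) is recomputed within each
#' category under the selected setting, and the resulting ICC distributions
#' (one value per feature, per category) are compared with the Mann-Whitney U
#' test (2 categories) or Kruskal-Wallis test (3+). Benjamini-Hochberg
#' correction is applied across the family of variables tested. Categories
#' with fewer than 3 lesions make the ICC incomputable: the variable is
#' flagged and excluded from the family.
#'
#' @param features Long feature table (index lesions).
#' @param clinical Clinical data.frame (lesion_id, psad, prostate_volume,
#'   pirads, isup, is_index).
#' @param setting_index The selected setting.
#' @param threshold Unused here; kept for symmetry with the grid tools.
#' @return data.frame: variable, test, statistic, p_raw, p_adjusted,
#'   significant, group_sizes, flagged.
#' @export
compare_icc_by_category <- function(features, clinical, setting_index,
                                    threshold = 0.75) {
  clinical <- clinical[clinical$is_index, , drop = FALSE]
  feats <- features[features$setting_index == setting_index &
                      features$lesion_id %in% clinical$lesion_id, ,
                    drop = FALSE]
  out <- list()
  for (v in clinical_variables()) {
    cat_v <- category_of(clinical, v)
    cats <- sort(unique(cat_v))
    sizes <- table(cat_v)
    if (length(cats) < 2 || any(sizes < 3)) {
      out[[v]] <- data.frame(variable = v, test = NA_character_,
                             statistic = NA_real_, p_raw = NA_real_,
                             group_sizes = paste(sizes, collapse = "/"),
                             flagged = TRUE, stringsAsFactors = FALSE)
      next
    }
    icc_dists <- lapply(cats, function(cc) {
      ids <- clinical$lesion_id[cat_v == cc]
      g <- build_grid(feats[feats$lesion_id %in% ids, , drop = FALSE])
      as.vector(g$icc)
    })
    if (length(cats) == 2) {
      r <- mann_whitney_u(icc_dists[[1]], icc_dists[[2]])
      out[[v]] <- data.frame(variable = v, test = "MannWhitneyU",
                             statistic = r$U, p_raw = r$p,
                             group_sizes = paste(sizes, collapse = "/"),
                             flagged = FALSE, stringsAsFactors = FALSE)
    } else {
      r <- kruskal_wallis(icc_dists)
      out[[v]] <- data.frame(variable = v, test = "KruskalWallis",
                             statistic = r$H, p_raw = r$p,
                             group_sizes = paste(sizes, collapse = "/"),
                             flagged = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_adjusted <- NA_real_
  ok <- !res$flagged
  if (any(ok)) res$p_adjusted[ok] <- benjamini_hochberg(res$p_raw[ok])
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < 0.05
  res
}

#' Compare baseline feature values across clinical categories
#'
#' Per feature and clinical variable, the scan-1 (baseline) feature values of
#' index lesions under the selected setting are compared across categories
#' with the Mann-Whitney U (2 categories) or Kruskal-Wallis (3+) test.
#' Benjamini-Hochberg correction is applied per variable across the 107
#' features (one family per clinical variable); set
#' \code{family = "global"} for a single family over all cells.
#'
#' @param features Long feature table (index lesions).
#' @param clinical Clinical data.frame.
#' @param setting_index The selected setting.
#' @param family "per_variable" (default) or "global".
#' @return data.frame: variable, feature, test, statistic, p_raw,
#'   p_adjusted, significant.
#' @export
compare_values_by_category <- function(features, clinical, setting_index,
                                       family = c("per_variable", "global")) {
  family <- match.arg(family)
  clinical <- clinical[clinical$is_index, , drop = FALSE]
  feats <- features[features$setting_index == setting_index &
                      features$scan == 1 &
                      features$lesion_id %in% clinical$lesion_id, ,
                    drop = FALSE]
  fnames <- sort(unique(feats$feature_name))
  out <- list()
  for (v in clinical_variables()) {
    cat_v <- category_of(clinical, v)
    cats <- sort(unique(cat_v))
    if (length(cats) < 2) next
    for (fn in fnames) {
      fv <- feats[feats$feature_name == fn, , drop = FALSE]
      vals <- fv$value[match(clinical$lesion_id, fv$lesion_id)]
      gs <- split(vals, cat_v)
      if (length(unique(round(vals, 12))) <= 1) {
        out[[length(out) + 1L]] <- data.frame(
          variable = v, feature = fn, test = "constant", statistic = NA_real_,
          p_raw = 1, stringsAsFactors = FALSE)
        next
      }
      if (length(cats) == 2) {
        r <- mann_whitney_u(gs[[1]], gs[[2]])
        out[[length(out) + 1L]] <- data.frame(
          variable = v, feature = fn, test = "MannWhitneyU",
          statistic = r$U, p_raw = r$p, stringsAsFactors = FALSE)
      } else {
        r <- kruskal_wallis(gs)
        out[[length(out) + 1L]] <- data.frame(
          variable = v, feature = fn, test = "KruskalWallis",
          statistic = r$H, p_raw = r$p, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (family == "per_variable") {
    res$p_adjusted <- NA_real_
    for (v in unique(res$variable)) {
      sel <- res$variable == v
      res$p_adjusted[sel] <- benjamini_hochberg(res$p_raw[sel])
    }
  } else {
    res$p_adjusted <- benjamini_hochberg(res$p_raw)
  }
  res$significant <- res$p_adjusted < 0.05
  res
}
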