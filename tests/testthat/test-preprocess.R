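test_that("the setting grid enumerates exactly the 48 unique combinations", {
  grid <- enumerate_settings()
  expect_equal(nrow(grid), 48L)
  expect_equal(grid$setting_index, 1:48)
  key <- with(grid, paste(discretization, binning, normalization, outlier_mode))
  expect_equal(anyDuplicated(key), 0L)
  # full Cartesian product: every legal tuple appears
  expect_setequal(unique(grid$binning[grid$discretization == "FBN"]),
                  c(16, 32, 64, 128))
  expect_setequal(unique(grid$binning[grid$discretization == "FBS"]),
                  c(5, 10, 20, 40))
  expect_equal(sum(grid$discretization == "FBN"), 24L)
  one <- grid[grid$discretization == "FBN" & grid$binning == 64 &
                grid$normalization == "NAR" & grid$outlier_mode == "OUT", ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$setting_index, 18L)
})

test_that("dual-reference normalization anchors the reference means", {
  roi <- random_roi(11, dims = c(8, 8, 4))
  fat <- array(FALSE, roi$dims); fat[1:2, 1:2, 1] <- TRUE
  mus <- array(FALSE, roi$dims); mus[7:8, 7:8, 4] <- TRUE
  v <- roi$volume
  v[fat] <- v[fat] + 400   # separate the reference means
  out <- normalize_dual_reference(v, fat, mus, anchors = c(0, 1000))
  expect_equal(mean(out[mus]), 0, tolerance = 1e-10)
  expect_equal(mean(out[fat]), 1000, tolerance = 1e-10)
  # affine invariance: normalizing 2v + 10 gives the identical result
  out2 <- normalize_dual_reference(2 * v + 10, fat, mus, anchors = c(0, 1000))
  expect_equal(as.vector(out2), as.vector(out), tolerance = 1e-9)
  # hand-derived two-point map: muscle 200, fat 800, anchors (0,1000): 500 -> 500
  vv <- array(500, c(2, 2, 2)); vv[fat2 <- array(c(TRUE, rep(FALSE, 7)), c(2,2,2))] <- 800
  mus2 <- array(c(FALSE, TRUE, rep(FALSE, 6)), c(2, 2, 2))
  vv[mus2] <- 200
  res <- normalize_dual_reference(vv, fat2, mus2, anchors = c(0, 1000))
  expect_equal(res[1, 2, 1], 500)
  expect_error(normalize_dual_reference(vv, fat2, fat2), "degenerate")
  expect_error(normalize_dual_reference(vv, array(FALSE, c(2, 2, 2)), mus2),
               "fat")
})

test_that("outlier filtering honors the mu +/- 3 sigma contract per mode", {
  vals <- c(rep(0, 99), 1000)          # mu = 10, sample sd = 100
  vol <- array(vals, c(10, 10, 1))
  mask <- array(TRUE, c(10, 10, 1))
  nof <- filter_outliers(vol, mask, "NoF")
  expect_identical(nof$volume, vol)
  expect_equal(nof$n_affected, 0L)
  out <- filter_outliers(vol, mask, "OUT")
  expect_equal(sum(out$mask), 99L)
  expect_false(out$mask[which(vol == 1000)])
  inr <- filter_outliers(vol, mask, "IN")
  expect_equal(max(inr$volume[mask]), 310)
  expect_equal(sum(inr$mask), 100L)    # IN never shrinks the mask
  expect_true(all(inr$volume[inr$mask] >= inr$mu - 3 * inr$sigma - 1e-12 &
                    inr$volume[inr$mask] <= inr$mu + 3 * inr$sigma + 1e-12))
  # nothing outside the range: IN and OUT are identities
  roi <- random_roi(3)
  for (mode in c("IN", "OUT")) {
    r <- filter_outliers(roi$volume, roi$mask, mode, n_sigma = 10)
    expect_identical(r$volume, roi$volume)
    expect_equal(sum(r$mask), sum(roi$mask))
  }
  expect_warning(filter_outliers(array(5, c(2, 2, 2)),
                                 array(TRUE, c(2, 2, 2)), "OUT"), "sigma")
})

test_that("FBN discretization follows the floor formula and is affine invariant", {
  v <- array(0, c(4, 1, 1)); v[, 1, 1] <- c(1, 2, 3, 4)
  m <- array(TRUE, c(4, 1, 1))
  d <- discretize_fbn(v, m, 2)
  expect_equal(d$levels[m], c(1, 1, 2, 2))
  expect_equal(d$ng, 2L)
  # affine invariance over random ROIs
  for (seed in 1:5) {
    roi <- random_roi(seed)
    a <- runif(1, 0.1, 5); b <- runif(1, -100, 100)
    d1 <- discretize_fbn(roi$volume, roi$mask, 16)
    d2 <- discretize_fbn(a * roi$volume + b, roi$mask, 16)
    expect_identical(d1$levels, d2$levels)
  }
  # constant ROI degenerates to a single level
  dc <- discretize_fbn(array(7, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 16)
  expect_true(all(dc$levels == 1))
  expect_equal(dc$ng, 1L)
  # top value clamped into the last bin
  dtop <- discretize_fbn(v, m, 4)
  expect_equal(max(dtop$levels[m]), 4)
})

test_that("FBS discretization anchors edges at bin-width multiples", {
  v <- array(0, c(3, 1, 1)); v[, 1, 1] <- c(10, 17, 25)
  m <- array(TRUE, c(3, 1, 1))
  d <- discretize_fbs(v, m, 5)
  expect_equal(d$levels[m], c(1, 2, 4))
  expect_equal(d$ng, 4L)
  # shifting by a whole bin width leaves levels unchanged
  d2 <- discretize_fbs(v + 5, m, 5)
  expect_equal(d2$levels[m], d$levels[m])
  # scaling doubles the occupied range (not scale invariant, by construction)
  d3 <- discretize_fbs(2 * v, m, 5)
  expect_gt(d3$ng, d$ng)
  # roi_minimum anchoring starts the first bin at the minimum
  d4 <- discretize_fbs(v + 2, m, 5, anchor = "roi_minimum")
  expect_equal(d4$levels[m], c(1, 2, 4))
})

test_that("apply_setting composes normalization, filtering and discretization", {
  cfg <- tiny_config(5)
  case <- generate_cohort(cfg)[[1]]
  grid <- enumerate_settings()
  # NAR/NoF/FBN16: two identity stages, equals direct FBN of the raw ROI
  s <- grid[grid$discretization == "FBN" & grid$binning == 16 &
              grid$normalization == "NAR" & grid$outlier_mode == "NoF", ]
  prep <- apply_setting(case, 1, s)
  direct <- discretize_fbn(case$scan1_volume, case$scan1_mask, 16)
  expect_identical(prep$disc$levels, direct$levels)
  # setting 18 shrinks the mask by exactly the out-of-range voxels
  s18 <- get_setting(18)
  expect_equal(setting_label(s18), "FBN64/NAR/OUT")
  prep18 <- apply_setting(case, 1, s18)
  x <- case$scan1_volume[case$scan1_mask]
  lo <- mean(x) - 3 * sd(x); hi <- mean(x) + 3 * sd(x)
  expect_equal(sum(prep18$mask), sum(x >= lo & x <= hi))
  # AR vs NAR is invisible to FBN when no voxels are removed
  sAR <- grid[grid$discretization == "FBN" & grid$binning == 64 &
                grid$normalization == "AR" & grid$outlier_mode == "NoF", ]
  sNAR <- grid[grid$discretization == "FBN" & grid$binning == 64 &
                 grid$normalization == "NAR" & grid$outlier_mode == "NoF", ]
  expect_identical(apply_setting(case, 1, sAR)$disc$levels,
                   apply_setting(case, 1, sNAR)$disc$levels)
})
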