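test_that("Mann-Whitney U: exact small-sample p-values match enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")
  set.seed(7)
  for (i in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p, oracle_mwu_exact(x, y), tolerance = 1e-12)
    # symmetry: swapping samples preserves p and reflects U
    sw <- mann_whitney_u(y, x)
    expect_equal(sw$p, got$p, tolerance = 1e-12)
    expect_equal(sw$U, nx * ny - got$U)
  }
  # identical samples: no evidence
  expect_gte(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1 - 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Mann-Whitney U: exact and normal approximation agree at n = 10 + 10", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, mean = runif(1, -1, 1))
    exact <- oracle_mwu_exact(x, y)
    approx <- mann_whitney_u(x, y)     # n = 20 > 12: normal approximation
    expect_equal(approx$method, "normal")
    expect_lt(abs(approx$p - exact), 0.02)
  }
})

test_that("Kruskal-Wallis matches hand rank computation and edge cases", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  r <- kruskal_wallis(groups)
  expect_equal(r$H, oracle_kw_h(groups), tolerance = 1e-12)
  expect_equal(r$df, 2)
  # hand value: rank sums 6, 15, 24 -> H = 12/(9*10)*(12+75+192) - 30 = 7.2
  expect_equal(r$H, 7.2)
  # three identical groups: H = 0, p = 1
  same <- list(c(1, 2), c(1, 2), c(1, 2))
  rs <- kruskal_wallis(same)
  expect_equal(rs$H, 0, tolerance = 1e-12)
  expect_equal(rs$p, 1)
  # two-group KW approximately equals the MWU normal approximation
  # (larger samples so the continuity correction in the MWU is negligible)
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(50); y <- rnorm(50, 0.3)
    pk <- kruskal_wallis(list(x, y))$p
    pm <- mann_whitney_u(x, y)$p
    expect_lt(abs(pk - pm), 0.01)
  }
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Benjamini-Hochberg equals brute-force step-up and p.adjust", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(31)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    got <- benjamini_hochberg(p)
    expect_lt(max(abs(got - oracle_bh(p))), 1e-12)
    expect_true(all(got >= p - 1e-15))
    expect_true(all(got <= 1))
  }
  p <- runif(50)
  expect_equal(benjamini_hochberg(p), stats::p.adjust(p, "BH"))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("category schemes apply the published cut-offs", {
  clin <- data.frame(lesion_id = sprintf("L%d", 1:6),
                     psad = c(0.10, 0.15, 0.16, 0.5, 0.05, 0.2),
                     prostate_volume = c(39.9, 40, 45, 20, 60, 35),
                     pirads = c(3, 4, 5, 3, 4, 5),
                     isup = c(0, 1, 2, 5, 0, 1),
                     is_index = TRUE)
  expect_equal(radrepro:::category_of(clin, "PSAD"),
               c("low", "low", "high", "high", "low", "high"))
  expect_equal(radrepro:::category_of(clin, "prostate_volume"),
               c("small", "enlarged", "enlarged", "small", "enlarged",
                 "small"))
  expect_equal(radrepro:::category_of(clin, "ISUP"),
               c("<1", "1", ">1", ">1", "<1", "1"))
})

test_that("null-calibrated comparisons keep the post-BH false-positive rate", {
  # categories independent of the feature values: over replicates, the
  # fraction of significant (variable) calls stays near the nominal level
  set.seed(17)
  n_rep <- 200
  sig <- 0; tested <- 0
  for (rep in seq_len(n_rep)) {
    n <- 40
    clin <- data.frame(
      lesion_id = sprintf("L%02d", 1:n),
      psad = rlnorm(n, -1.4, 0.7), prostate_volume = rlnorm(n, 3.8, 0.4),
      pirads = sample(3:5, n, TRUE), isup = sample(0:5, n, TRUE),
      is_index = TRUE)
    tab <- simulate_feature_table(n, 0.5, n_features = 6, seed = 9000 + rep)
    feats <- do.call(rbind, lapply(1:6, function(f)
      do.call(rbind, lapply(1:2, function(s)
        data.frame(lesion_id = clin$lesion_id, scan = s, setting_index = 1L,
                   feature_name = sprintf("F%02d", f),
                   value = tab[, s, f])))))
    res <- compare_values_by_category(feats, clin, 1L)
    sig <- sig + sum(res$significant)
    tested <- tested + nrow(res)
  }
  rate <- sig / tested
  mc_se <- sqrt(0.05 * 0.95 / tested)
  expect_lte(rate, 0.05 + 2 * mc_se)
})

test_that("ICC-by-category flags small categories and detects planted effects", {
  # two categories with identical lesion subsets give p = 1
  n <- 12
  clin <- data.frame(lesion_id = sprintf("L%02d", 1:n),
                     psad = rep(c(0.1, 0.3), each = n / 2),
                     prostate_volume = 50, pirads = 4, isup = 2,
                     is_index = TRUE)
  tab <- simulate_feature_table(n, 0.5, n_features = 5, seed = 44)
  feats <- do.call(rbind, lapply(1:5, function(f)
    do.call(rbind, lapply(1:2, function(s)
      data.frame(lesion_id = clin$lesion_id, scan = s, setting_index = 1L,
                 feature_name = sprintf("F%02d", f), value = tab[, s, f])))))
  res <- compare_icc_by_category(feats, clin, 1L)
  expect_s3_class(res, "data.frame")
  # single-category variables (volume, PIRADS, ISUP here) cannot be tested
  expect_true(res$flagged[res$variable == "prostate_volume"])
  expect_false(res$flagged[res$variable == "PSAD"])
  # planted reliability difference: low-PSAD reliable, high-PSAD not
  set.seed(55)
  hits <- 0
  n_rep <- 25
  for (rep in seq_len(n_rep)) {
    lo <- simulate_feature_table(25, 0.9, n_features = 40,
                                 seed = 100 + rep)
    hi <- simulate_feature_table(25, 0.3, n_features = 40,
                                 seed = 500 + rep)
    clin2 <- data.frame(lesion_id = sprintf("L%02d", 1:50),
                        psad = rep(c(0.1, 0.3), each = 25),
                        prostate_volume = 50, pirads = 4, isup = 2,
                        is_index = TRUE)
    feats2 <- do.call(rbind, lapply(1:40, function(f)
      do.call(rbind, lapply(1:2, function(s)
        data.frame(lesion_id = clin2$lesion_id, scan = s, setting_index = 1L,
                   feature_name = sprintf("F%02d", f),
                   value = c(lo[, s, f], hi[, s, f]))))))
    r2 <- compare_icc_by_category(feats2, clin2, 1L)
    if (isTRUE(r2$significant[r2$variable == "PSAD"])) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.8)
})

test_that("constant features give p = 1 for every variable", {
  n <- 10
  clin <- data.frame(lesion_id = sprintf("L%02d", 1:n),
                     psad = runif(n, 0.05, 0.5),
                     prostate_volume = runif(n, 20, 70),
                     pirads = sample(3:5, n, TRUE),
                     isup = sample(0:5, n, TRUE), is_index = TRUE)
  feats <- do.call(rbind, lapply(1:2, function(s)
    data.frame(lesion_id = clin$lesion_id, scan = s, setting_index = 1L,
               feature_name = "Fconst", value = 3.14)))
  res <- compare_values_by_category(feats, clin, 1L)
  expect_true(all(res$p_raw == 1))
  expect_true(all(!res$significant))
})
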