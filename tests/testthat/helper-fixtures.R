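# Small deterministic fixtures built in code.

# random small ROI: continuous volume plus a blobby mask of <= ~max_vox voxels
random_roi <- function(seed, dims = c(6, 6, 4), p_mask = 0.6) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  vol <- array(stats::rnorm(prod(dims), 100, 25), dims)
  mask <- array(stats::runif(prod(dims)) < p_mask, dims)
  if (sum(mask) < 4) mask[1:4] <- TRUE
  list(volume = vol, mask = mask, dims = dims)
}

# fast tiny cohort configuration for end-to-end tests
tiny_config <- function(seed = 1L, n_patients = 6L, total_lesions = 8L,
                        ...) {
  sim_config(n_patients = n_patients, total_lesions = total_lesions,
             grid_shape = c(20L, 20L, 8L),
             lesion_radius_range = c(2.5, 4),
             smoothing_vox = c(1, 1, 0.5),
             seed = seed, ...)
}

expect_rel_equal <- function(got, want, tol = 1e-6, scale_floor = 1e-8) {
  denom <- pmax(abs(want), scale_floor)
  expect_true(all(abs(got - want) / denom < tol),
              label = paste0("max rel diff ",
                             format(max(abs(got - want) / denom))))
}
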