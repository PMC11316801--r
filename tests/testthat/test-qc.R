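test_that("session inclusion reproduces the worked example and boundaries", {
  # example session: 29 CL, 9 IR, 7 IL, 34 CR -> lowest count 7, included
  si <- check_session_inclusion(trials_from_counts(29, 9, 7, 34))
  expect_equal(si$min_count, 7L)
  expect_equal(si$performance, 63 / 79)
  expect_true(si$included)
  # equal counts: min rule passes but performance is exactly 0.5 -> excluded
  si2 <- check_session_inclusion(trials_from_counts(2, 2, 2, 2))
  expect_equal(si2$performance, 0.5)
  expect_false(si2$included)
  # any type below 2 trials -> excluded
  expect_false(check_session_inclusion(trials_from_counts(5, 5, 1, 5))$included)
  # aborted trials do not count
  si3 <- check_session_inclusion(trials_from_counts(29, 9, 7, 34, n_aborted = 5))
  expect_equal(si3$performance, 63 / 79)
  expect_error(check_session_inclusion(trials_from_counts(0, 0, 0, 0, 3)),
               "no non-aborted")
})

test_that("reliability test accepts consistent and rejects degenerate cells", {
  bins <- 60L
  resp <- sin(seq(0, 3 * pi, length.out = bins))
  m <- matrix(rep(resp, 12), nrow = 12, byrow = TRUE)
  rt <- reliability_test(m, n_iter = 100, seed = 2)
  expect_equal(rt$cc_true, 1)
  expect_true(rt$reliable)
  expect_length(rt$null_ccs, 100L)
  # constant trace: undefined correlation, not reliable, flagged
  rt2 <- reliability_test(matrix(5, 12, bins), n_iter = 50, seed = 3)
  expect_false(rt2$reliable)
  expect_true(rt2$degenerate)
  expect_error(reliability_test(m[1:3, ]), "at least 4")
})

test_that("reliability test holds its nominal false-positive rate", {
  # quick version (300 cells); the full 1000-cell calibration runs in the
  # acceptance suite
  set.seed(4)
  flags <- vapply(1:300, function(k)
    reliability_test(matrix(rnorm(16 * 45), 16, 45),
                     n_iter = 100, seed = k)$reliable, logical(1))
  expect_equal(mean(flags), 0.05, tolerance = 0.03 / 0.05)
})

test_that("compute_ssi basic properties", {
  set.seed(5)
  a <- matrix(runif(900), 30, 30)
  expect_equal(compute_ssi(a, a), 1)
  inv <- max(a) + min(a) - a            # contrast inversion
  expect_lt(compute_ssi(a, inv), 1)
  expect_error(compute_ssi(a, a[1:20, 1:20]), "shapes")
})

test_that("roi stability decisions are invariant to a constant offset", {
  cfg <- task_config(n_cells = 10L, n_trials = 10L)
  roi <- generate_roi_patches(cfg, n_unstable = 4L, seed = 17)
  for (i in c(1L, roi$unstable_ids[1])) {
    nw <- sample_null_windows(roi$fields[[2]], roi$patch_px, n = 60,
                              exclude_center = roi$centers[[2]][i, ],
                              seed = 200 + i)
    r0 <- roi_stability_test(roi$patches[[1]][i, , ],
                             roi$patches[[2]][i, , ], nw)
    r1 <- roi_stability_test(roi$patches[[1]][i, , ] + 10,
                             roi$patches[[2]][i, , ] + 10,
                             lapply(nw, function(w) w + 10))
    expect_identical(r0$stable, r1$stable)
    expect_lt(abs(r0$ssi_true - r1$ssi_true), 0.05)
  }
})

test_that("compute_ssi matches the scikit-image reference to 1e-6", {
  set.seed(6)
  a <- matrix(runif(1600), 40, 40)
  b <- 0.6 * a + matrix(rnorm(1600, 0, 0.2), 40, 40)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write.table(a, fa, sep = ",", row.names = FALSE, col.names = FALSE)
  write.table(b, fb, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf("
import numpy as np
from skimage.metrics import structural_similarity
a = np.loadtxt('%s', delimiter=',')
b = np.loadtxt('%s', delimiter=',')
dr = max(a.max(), b.max()) - min(a.min(), b.min())
print('%%.12f' %% structural_similarity(a, b, gaussian_weights=True, sigma=1.5,
      use_sample_covariance=False, data_range=dr))
", fa, fb)
  ref <- as.numeric(run_python_oracle(code))
  expect_equal(compute_ssi(a, b), ref, tolerance = 1e-6 / abs(ref))
})

test_that("roi_stability_test separates stable from relocated ROIs", {
  cfg <- task_config(n_cells = 25L, n_trials = 10L)
  roi <- generate_roi_patches(cfg, n_unstable = 10L, seed = 7)
  stable_ids <- setdiff(seq_len(25), roi$unstable_ids)
  verdict <- function(i, metric = "ssim") {
    nw <- sample_null_windows(roi$fields[[2]], roi$patch_px, n = 60,
                              exclude_center = roi$centers[[2]][i, ],
                              seed = 100 + i)
    roi_stability_test(roi$patches[[1]][i, , ], roi$patches[[2]][i, , ],
                       nw, metric = metric)$stable
  }
  frac_stable <- mean(vapply(stable_ids, verdict, logical(1)))
  frac_unstable <- mean(vapply(roi$unstable_ids, verdict, logical(1)))
  expect_gte(frac_stable, 0.95)
  expect_lte(frac_unstable, 0.10)
  # both similarity metrics agree on clear cases
  v_ssim <- vapply(seq_len(25), verdict, logical(1))
  v_corr <- vapply(seq_len(25), verdict, logical(1), metric = "corr2d")
  expect_gte(mean(v_ssim == v_corr), 0.9)
  expect_error(roi_stability_test(roi$patches[[1]][1, , ],
                                  roi$patches[[2]][1, , ],
                                  list(roi$patches[[1]][2, , ])),
               "50 null windows")
})

test_that("select_cells applies the pairwise and strict gates", {
  reliable <- matrix(TRUE, 6, 5)
  stable <- matrix(TRUE, 6, 5)
  inc <- rep(TRUE, 5)
  sel <- select_cells(reliable, stable, inc)
  expect_equal(sel$pairs[["3"]], 1:6)
  expect_equal(sel$strict, 1:6)
  # a cell reliable only on day 1 is excluded from every pair
  reliable2 <- reliable; reliable2[2, 2:5] <- FALSE
  sel2 <- select_cells(reliable2, stable, inc)
  for (k in as.character(2:5)) expect_false(2L %in% sel2$pairs[[k]])
  expect_false(2L %in% sel2$strict)
  # strict set is a subset of every pairwise set
  reliable3 <- matrix(sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(.8, .2)), 6, 5)
  stable3 <- matrix(sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(.8, .2)), 6, 5)
  sel3 <- select_cells(reliable3, stable3, inc)
  for (k in as.character(2:5))
    expect_true(all(sel3$strict %in% sel3$pairs[[k]]))
  # failed behavioral inclusion empties the affected pairs
  inc4 <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  sel4 <- select_cells(reliable, stable, inc4)
  expect_length(sel4$pairs[["2"]], 0L)
  expect_gt(length(sel4$pairs[["3"]]), 0L)
})
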