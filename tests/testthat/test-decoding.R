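test_that("variable_labels implements the three binary partitions", {
  # CL: context 1, left choice, correct outcome
  expect_equal(variable_labels("CL", "context"), 1L)
  expect_equal(variable_labels("CL", "motor"), 1L)
  expect_equal(variable_labels("CL", "post_decision_outcome"), 1L)
  # IR: context 1, right choice, incorrect outcome
  expect_equal(variable_labels("IR", "context"), 1L)
  expect_equal(variable_labels("IR", "motor"), 2L)
  expect_equal(variable_labels("IR", "post_decision_outcome"), 2L)
  expect_equal(variable_labels(c("IL", "CR"), "context"), c(2L, 2L))
  expect_equal(variable_labels(c("IL", "CR"), "motor"), c(1L, 2L))
  expect_equal(variable_labels(c("IL", "CR"), "post_trial_outcome"), c(2L, 1L))
  # the three rules are pairwise distinct partitions
  tt <- c("CL", "IR", "IL", "CR")
  parts <- sapply(c("context", "motor", "post_decision_outcome"),
                  function(v) variable_labels(tt, v))
  expect_false(identical(parts[, 1], parts[, 2]))
  expect_false(identical(parts[, 1], parts[, 3]))
  expect_false(identical(parts[, 2], parts[, 3]))
  expect_error(variable_labels("aborted", "context"), "aborted")
})

test_that("homogenize_and_split balances types from disjoint halves", {
  types <- c(rep("CL", 19), rep("IR", 7), rep("IL", 6), rep("CR", 23))
  hs <- homogenize_and_split(types, seed = 1)
  expect_equal(hs$target, 6L)
  for (ty in c("CL", "IR", "IL", "CR")) {
    expect_equal(sum(types[hs$train] == ty), 6L)
    expect_equal(sum(types[hs$test] == ty), 6L)
  }
  # underlying trials never shared
  expect_length(intersect(hs$train, hs$test), 0L)
  expect_length(intersect(hs$train_half, hs$test_half), 0L)
  expect_true(all(hs$train %in% hs$train_half))
  expect_true(all(hs$test %in% hs$test_half))
  # equal counts of 8 give halves of 4 per type
  hs2 <- homogenize_and_split(rep(c("CL", "IR", "IL", "CR"), each = 8), seed = 2)
  expect_equal(length(hs2$train_half), 16L)
  expect_error(homogenize_and_split(c("CL", "IR", "IL", "CR")), "at least 2")
})

test_that("train/test disjointness holds across audited iterations", {
  types <- rep(c("CL", "IR", "IL", "CR"), times = c(9, 5, 4, 11))
  for (k in 1:25) {
    hs <- homogenize_and_split(types, seed = k)
    expect_length(intersect(unique(hs$train), unique(hs$test)), 0L)
  }
})

test_that("the linear SVM matches the scikit-learn reference", {
  set.seed(20)
  X <- rbind(matrix(rnorm(90, 0.8), 30, 3), matrix(rnorm(90, -0.8), 30, 3))
  y <- rep(c(1L, 2L), each = 30)
  fit <- codedrift:::svm_fit(X, y, C = 1, max_epochs = 100000L, tol = 1e-8)
  fx <- tempfile(fileext = ".csv")
  write.table(cbind(X, ifelse(y == 1L, 1, -1)), fx, sep = ",",
              row.names = FALSE, col.names = FALSE)
  out <- run_python_oracle(sprintf("
import numpy as np
from sklearn.svm import LinearSVC
d = np.loadtxt('%s', delimiter=',')
m = LinearSVC(C=1.0, loss='hinge', fit_intercept=True, intercept_scaling=1.0,
              max_iter=200000, tol=1e-9).fit(d[:, :3], d[:, 3])
print(' '.join('%%.8f' %% v for v in list(m.coef_[0]) + [m.intercept_[0]]))
", fx))
  ref <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  expect_equal(c(fit$w, fit$b), ref, tolerance = 5e-3)
})

test_that("decoding reaches ceiling on separable data and chance on shuffled", {
  # perfectly separated synthetic classes in the context window
  tens <- make_labeled_tensor(n_cells = 10, trials_per_type = 16, n_bins = 30,
                              signal_cells = 1:5, variable = "context",
                              amp = 8, signal_bins = 10:25, seed = 30)
  cv <- decode_across_days(tens, NULL, "context", bins = 12:22, n_iter = 30,
                           seed = 31)
  expect_gte(mean(cv$mean_performance), 0.95)
  expect_true(all(cv$ci_low <= cv$mean_performance &
                    cv$mean_performance <= cv$ci_high))
  # same activity decoded against an orthogonal partition: chance
  cvm <- decode_across_days(tens, NULL, "motor", bins = 12:22, n_iter = 30,
                            seed = 32)
  expect_equal(mean(cvm$mean_performance), 0.5, tolerance = 0.1)
  # pre-signal bins of tuned cells: chance
  cv0 <- decode_across_days(tens, NULL, "context", bins = 1:8, n_iter = 30,
                            seed = 33)
  expect_equal(mean(cv0$mean_performance), 0.5, tolerance = 0.1)
})

test_that("decoding curves are deterministic given the seed", {
  tens <- make_labeled_tensor(n_cells = 6, trials_per_type = 6, n_bins = 15,
                              seed = 35)
  c1 <- decode_across_days(tens, NULL, "context", n_iter = 10, seed = 7)
  c2 <- decode_across_days(tens, NULL, "context", n_iter = 10, seed = 7)
  expect_identical(c1$mean_performance, c2$mean_performance)
  expect_identical(c1$iter_performance, c2$iter_performance)
})

test_that("significant_encoding applies the run and region rules", {
  mk_curve <- function(ci_low, variable = "context", bins = seq_along(ci_low)) {
    structure(list(mean_performance = ci_low + 0.1, ci_low = ci_low,
                   ci_high = ci_low + 0.2, bins = bins,
                   bin_time_s = (bins - 1) * 0.1, variable = variable),
              class = "decoding_curve")
  }
  expect_true(significant_encoding(mk_curve(rep(0.6, 90)))$significant)
  # a single 4-bin qualifying run is not enough
  ci <- rep(0.4, 90); ci[10:13] <- 0.6
  expect_false(significant_encoding(mk_curve(ci))$significant)
  # outcome run spanning bins 65-75 is post-trial outcome
  ci2 <- rep(0.4, 90); ci2[65:75] <- 0.6
  call2 <- significant_encoding(mk_curve(ci2, "post_decision_outcome"),
                                trial_end_bin = 61L)
  expect_true(call2$significant)
  expect_equal(call2$assigned_variables, "post_trial_outcome")
  # outcome run before trial end is post-decision outcome
  ci3 <- rep(0.4, 90); ci3[35:45] <- 0.6
  call3 <- significant_encoding(mk_curve(ci3, "post_decision_outcome"),
                                trial_end_bin = 61L)
  expect_equal(call3$assigned_variables, "post_decision_outcome")
  # runs in both regions assign both variables
  ci4 <- rep(0.4, 90); ci4[35:45] <- 0.6; ci4[65:75] <- 0.6
  call4 <- significant_encoding(mk_curve(ci4, "post_trial_outcome"),
                                trial_end_bin = 61L)
  expect_setequal(call4$assigned_variables,
                  c("post_decision_outcome", "post_trial_outcome"))
})

test_that("pseudopopulation decoding pools information across experiments", {
  t1 <- make_labeled_tensor(n_cells = 8, trials_per_type = 12, n_bins = 12,
                            signal_cells = 1:4, variable = "context",
                            amp = 6, signal_bins = 4:9, seed = 40)
  t2 <- make_labeled_tensor(n_cells = 8, trials_per_type = 14, n_bins = 12,
                            signal_cells = 1:4, variable = "context",
                            amp = 6, signal_bins = 4:9, seed = 41)
  cv <- pseudopopulation_decode(list(t1, t2), NULL, "context",
                                n_pseudo = 20, bins = 5:8, n_iter = 15,
                                seed = 42)
  expect_gte(mean(cv$mean_performance), 0.93)
  expect_equal(cv$unit, "pseudopopulation")
  # all-null cells decode at chance
  n1 <- make_labeled_tensor(n_cells = 8, trials_per_type = 6, n_bins = 12,
                            seed = 43)
  n2 <- make_labeled_tensor(n_cells = 8, trials_per_type = 6, n_bins = 12,
                            seed = 44)
  cvn <- pseudopopulation_decode(list(n1, n2), NULL, "context",
                                 n_pseudo = 20, bins = 5:8, n_iter = 15,
                                 seed = 45)
  expect_equal(mean(cvn$mean_performance), 0.5, tolerance = 0.1)
  expect_error(pseudopopulation_decode(list(t1), NULL, "context"),
               "at least 2 experiments")
})

test_that("more informative cells never hurt pseudo-population decoding", {
  perfs <- vapply(c(4, 12, 24), function(n_sig) {
    t1 <- make_labeled_tensor(n_cells = 30, trials_per_type = 6, n_bins = 10,
                              signal_cells = seq_len(n_sig), amp = 1.2,
                              variable = "context", signal_bins = 3:8,
                              seed = 50)
    t2 <- make_labeled_tensor(n_cells = 30, trials_per_type = 6, n_bins = 10,
                              signal_cells = seq_len(n_sig), amp = 1.2,
                              variable = "context", signal_bins = 3:8,
                              seed = 51)
    cv <- pseudopopulation_decode(list(t1, t2), NULL, "context",
                                  n_pseudo = 16, bins = 4:7, n_iter = 10,
                                  seed = 52)
    mean(cv$mean_performance)
  }, numeric(1))
  expect_true(all(diff(perfs) > -0.05))
  expect_gt(perfs[3], perfs[1])
})

test_that("subsample controls return working subsets", {
  tens <- make_labeled_tensor(n_cells = 20, trials_per_type = 16, n_bins = 90,
                              signal_cells = 1:12, variable = "context",
                              amp = 6, signal_bins = 16:31, seed = 60)
  eq <- subsample_controls(tens, "context", mode = "equal_n", n = 20,
                           n_iter = 8, seed = 61)
  expect_equal(eq$cells, 1:20)      # n = available returns the identity subset
  mp <- subsample_controls(tens, "context", mode = "match_performance",
                           target = 0.9, n_iter = 8, seed = 62)
  expect_true(mp$success)
  expect_gte(mp$performance, 0.9 - 0.02)
  expect_lte(length(mp$cells), 20L)
  # unreachable target is flagged rather than returned
  null_tens <- make_labeled_tensor(n_cells = 10, trials_per_type = 8,
                                   n_bins = 90, seed = 63)
  bad <- subsample_controls(null_tens, "context", mode = "match_performance",
                            target = 0.9, n_iter = 8, seed = 64)
  expect_false(bad$success)
  expect_length(bad$cells, 0L)
})
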