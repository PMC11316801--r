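test_that("trial schedule satisfies the trial-type mapping and frame layout", {
  cfg <- task_config(n_trials = 200L)
  tr <- generate_trial_schedule(cfg, seed = 7)
  expect_equal(nrow(tr), 200L)
  live <- tr[tr$trial_type != "aborted", ]
  expect_equal(live$trial_type,
               ifelse(live$context == 1L,
                      ifelse(live$choice == "left", "CL", "IR"),
                      ifelse(live$choice == "left", "IL", "CR")))
  expect_true(all((live$outcome == "correct") ==
                    (live$trial_type %in% c("CL", "CR"))))
  # contiguous frames; start < decision < end <= reward_end
  expect_equal(tr$start_frame[-1], tr$reward_end_frame[-nrow(tr)] + 1L)
  expect_true(all(tr$start_frame < tr$decision_frame &
                    tr$decision_frame < tr$end_frame &
                    tr$end_frame <= tr$reward_end_frame))
  # aborted trials carry no choice
  expect_true(all(tr$choice[tr$trial_type == "aborted"] == "none"))
})

test_that("anti-repeat ramp suppresses context repeats below the 0.5 null rate", {
  # gate disabled (window larger than the session): the ramp alone governs
  # context presentation; the bias gate by design *forces* repeats, so it is
  # exercised separately below
  cfg <- task_config(n_trials = 10000L, target_performance = 0.5,
                     bias_window = 20000L)
  tr <- generate_trial_schedule(cfg, seed = 11)
  rep_frac <- mean(diff(tr$context) == 0)
  expect_lt(rep_frac, 0.5)
})

test_that("bias gate shows the context rewarding the non-preferred side", {
  # an agent that almost always turns left should be steered to context 2
  cfg <- task_config(n_trials = 400L, target_performance = 0.97,
                     abort_rate = 0)
  tr <- generate_trial_schedule(cfg, seed = 13)
  # after a strongly one-sided stretch the next context must reward the
  # other side
  n <- nrow(tr)
  for (t in 11:n) {
    w <- tr$choice[(t - 10):(t - 1)]
    nl <- sum(w == "left"); nr <- sum(w == "right")
    if (nl > 2 * nr) expect_identical(tr$context[t], 2L)
    if (nr > 2 * nl) expect_identical(tr$context[t], 1L)
  }
})

test_that("realized behavioral performance concentrates on the target", {
  cfg <- task_config(n_trials = 10000L, target_performance = 0.74)
  tr <- generate_trial_schedule(cfg, seed = 3)
  live <- tr[tr$trial_type != "aborted", ]
  expect_equal(mean(live$outcome == "correct"), 0.74, tolerance = 0.03 / 0.74)
  # conservation: per-type counts plus aborted equal n_trials
  expect_equal(sum(table(tr$trial_type)), 10000L)
})

test_that("schedule rejects invalid configurations", {
  expect_error(task_config(n_trials = -5), "positive")
  expect_error(task_config(target_performance = 0.4), "0.5")
  expect_error(task_config(noise_sd = -1), "negative")
})

test_that("tuning amplitudes follow the per-variable decay law", {
  cfg <- task_config(n_cells = 400L, turnover_prob = 0)
  taus <- c(context = 3, motor = 1, post_decision_outcome = 2,
            post_trial_outcome = Inf)
  tun <- make_drifting_tuning(cfg, taus, seed = 5)
  tuned <- which(!is.na(tun$variable[, 1L]))
  expect_gt(length(tuned), 100L)
  for (i in tuned[1:50]) {
    v <- tun$variable[i, 1L]
    expected <- tun$amplitude[i, 1L] *
      if (is.finite(taus[[v]])) exp((1 - 1:5) / taus[[v]]) else rep(1, 5)
    expect_equal(tun$amplitude[i, ], expected, tolerance = 1e-12)
  }
  # log amplitude exactly linear in day with slope -1/tau
  i <- tuned[tun$variable[tuned, 1L] == "context"][1]
  slopes <- diff(log(tun$amplitude[i, ]))
  expect_equal(slopes, rep(-1 / 3, 4), tolerance = 1e-12)
})

test_that("tau = 1 halves-to-1/e and turnover retention is binomial", {
  cfg <- task_config(n_cells = 1000L, prop_tuned = 1, turnover_prob = 0.2)
  taus <- c(context = 1, motor = 1, post_decision_outcome = 1,
            post_trial_outcome = 1)
  tun <- make_drifting_tuning(cfg, taus, seed = 9)
  kept <- tun$assigned_day[, 2L] == 1L & !is.na(tun$variable[, 1L])
  ratio <- tun$amplitude[kept, 2L] / tun$amplitude[kept, 1L]
  expect_equal(unname(ratio), rep(exp(-1), sum(kept)), tolerance = 1e-12)
  # ~800 of 1000 retain tuning on day 2, +-3 binomial sd
  n_retained <- sum(tun$assigned_day[, 2L] == 1L)
  expect_lt(abs(n_retained - 800), 3 * sqrt(1000 * 0.2 * 0.8))
  expect_error(make_drifting_tuning(cfg, c(context = -1, motor = 1,
                                           post_decision_outcome = 1,
                                           post_trial_outcome = 1)),
               "positive")
})

test_that("zero-amplitude, zero-noise activity is constant at baseline", {
  cfg <- task_config(n_cells = 3L, n_trials = 10L, prop_tuned = 0,
                     noise_sd = 0, neuropil_alpha_true = 0)
  tun <- make_drifting_tuning(cfg, seed = 1)
  tr <- generate_trial_schedule(cfg, seed = 2)
  act <- simulate_day_activity(tun, tr, cfg, day = 1, seed = 3)
  for (i in 1:3)
    expect_equal(act$f_soma[i, ], rep(tun$baseline[i], ncol(act$f_soma)),
                 tolerance = 1e-12)
})

test_that("trial-averaged class difference matches the generator's closed form", {
  cfg <- task_config(n_cells = 30L, n_trials = 40L, noise_sd = 0,
                     amp_jitter_sdlog = 0, event_prob = 1,
                     neuropil_alpha_true = 0, turnover_prob = 0)
  tun <- make_drifting_tuning(cfg, seed = 21)
  tr <- generate_trial_schedule(cfg, seed = 22)
  act <- simulate_day_activity(tun, tr, cfg, day = 1, seed = 23)
  i <- which(tun$variable[, 1L] == "context")[1]
  expect_false(is.na(i))
  # independent oracle: direct convolution of the known kernel with the
  # normalized exponential calcium kernel
  kern <- tun$kernels$context[i, ]
  tau_fr <- cfg$calcium_tau_s * cfg$frame_rate_hz
  ck <- exp(-(0:(ceiling(5 * tau_fr) - 1)) / tau_fr); ck <- ck / sum(ck)
  expected_shape <- numeric(length(kern))
  for (b in seq_along(kern)) {
    idx <- b - seq_along(ck) + 1
    ok <- idx >= 1
    expected_shape[b] <- sum(kern[idx[ok]] * ck[ok])
  }
  A <- tun$amplitude[i, 1L]
  dff <- compute_dff(act$f_soma[i, ], tun$baseline[i])
  tens <- align_to_trials(dff, tr, c(0, 9), 10)
  cls <- variable_labels(attr(tens, "labels"), "context")
  pref <- tun$pref_class[i, 1L]
  diff_obs <- colMeans(matrix(tens[1, cls == pref, ], ncol = 90)) -
    colMeans(matrix(tens[1, cls != pref, ], ncol = 90))
  expect_equal(diff_obs, A * expected_shape, tolerance = 1e-6)
})

test_that("neuropil contamination weight is recoverable downstream", {
  cfg <- task_config(n_cells = 6L, n_trials = 60L, neuropil_alpha_true = 0.7)
  tun <- make_drifting_tuning(cfg, seed = 31)
  tr <- generate_trial_schedule(cfg, seed = 32)
  act <- simulate_day_activity(tun, tr, cfg, day = 1, seed = 33)
  a_hat <- vapply(1:6, function(i)
    estimate_alpha(act$f_soma[i, ], act$f_neuropil[i, ]), numeric(1))
  expect_equal(mean(a_hat), 0.7, tolerance = 0.05 / 0.7)
})

test_that("experiment bundles are deterministic and dimensionally consistent", {
  cfg <- small_config()
  b1 <- generate_experiment(cfg, seed = 44)
  b2 <- generate_experiment(cfg, seed = 44)
  expect_identical(b1, b2)
  expect_length(b1$days, 3L)
  ncells <- vapply(b1$days, function(d) nrow(d$f_soma), integer(1))
  expect_true(all(ncells == cfg$n_cells))
  for (d in b1$days) {
    expect_true(all(is.finite(d$f_soma)))
    expect_true(all(d$trials$reward_end_frame < ncol(d$f_soma)))
  }
})

test_that("default sessions pass behavioral inclusion", {
  ok <- 0L
  for (s in 1:10) {
    tr <- generate_trial_schedule(task_config(), seed = s)
    ok <- ok + check_session_inclusion(tr)$included
  }
  expect_gte(ok, 9L)
})

test_that("ROI patches: stable cells identical without jitter/noise, SSI = 1", {
  cfg <- task_config(n_cells = 8L, n_trials = 10L)
  roi <- generate_roi_patches(cfg, n_unstable = 0L, seed = 5,
                              jitter_px = 0L, patch_noise_sd = 0)
  for (i in 1:8) {
    expect_identical(roi$patches[[1]][i, , ], roi$patches[[3]][i, , ])
    expect_equal(compute_ssi(roi$patches[[1]][i, , ], roi$patches[[5]][i, , ]), 1)
  }
  expect_error(generate_roi_patches(cfg, n_unstable = 20L, seed = 1),
               "exceeds")
})
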