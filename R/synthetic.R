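#' Simulate a virtual T-maze trial schedule
#'
#' Generates one session's trial table for an agent that chooses the
#' rewarded side with probability `target_performance`. Context presentation
#' follows the anti-repeat ramp (the probability of repeating the current
#' context falls linearly from 50% to 0% over `anti_repeat_span` consecutive
#' repeats) and a response-bias gate: when, over the trailing `bias_window`
#' responses, one side exceeds double the other, the context rewarding the
#' non-preferred side is shown until the bias clears.
#'
#' @param config a [task_config()].
#' @param seed integer seed; the schedule is deterministic given
#'   `(config, seed)`.
#' @return A data.frame of trial records: `index`, `context` (1/2), `choice`
#'   (`left`/`right`/`none`), `outcome`, `trial_type` (`CL`, `IR`, `IL`,
#'   `CR`, `aborted`), and 0-based `start_frame`, `decision_frame`,
#'   `end_frame`, `reward_end_frame`. Consecutive trials are contiguous:
#'   each start frame is the previous `reward_end_frame + 1`.
#' @export
generate_trial_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  with_seed(seed, {
    n <- config$n_trials
    context <- integer(n); choice <- character(n)
    run_ctx <- 0L; run_len <- 0L
    responses <- character(0)  # non-aborted choices, in order

    for (t in seq_len(n)) {
      gate_ctx <- 0L
      if (length(responses) >= config$bias_window) {
        w <- utils::tail(responses, config$bias_window)
        nl <- sum(w == "left"); nr <- sum(w == "right")
        if (nl > 2 * nr) gate_ctx <- 2L   # left-biased: show right-rewarded maze
        if (nr > 2 * nl) gate_ctx <- 1L   # right-biased: show left-rewarded maze
      }
      if (gate_ctx > 0L) {
        ctx <- gate_ctx
      } else if (run_len == 0L) {
        ctx <- sample(1:2, 1L)
      } else {
        p_rep <- 0.5 * max(0, (config$anti_repeat_span - run_len) /
                                (config$anti_repeat_span - 1))
        ctx <- if (runif(1) < p_rep) run_ctx else 3L - run_ctx
      }
      if (ctx == run_ctx) run_len <- run_len + 1L else { run_ctx <- ctx; run_len <- 1L }
      context[t] <- ctx

      if (runif(1) < config$abort_rate) {
        choice[t] <- "none"
      } else {
        correct_side <- if (ctx == 1L) "left" else "right"
        wrong_side <- if (ctx == 1L) "right" else "left"
        choice[t] <- if (runif(1) < config$target_performance) correct_side else wrong_side
        responses <- c(responses, choice[t])
      }
    }

    trial_type <- trial_type_of(context, choice)
    outcome <- ifelse(choice == "none", "aborted",
                      ifelse(trial_type %in% c("CL", "CR"), "correct", "incorrect"))
    start_frame <- (seq_len(n) - 1L) * config$trial_frames
    data.frame(
      index = seq_len(n) - 1L,
      context = context, choice = choice, outcome = outcome,
      trial_type = trial_type,
      start_frame = start_frame,
      decision_frame = start_frame + config$decision_frame_offset,
      end_frame = start_frame + config$end_frame_offset,
      reward_end_frame = start_frame + config$trial_frames - 1L,
      stringsAsFactors = FALSE
    )
  })
}

# class of each trial type under a task variable's binary partition
# (context: {CL,IR} vs {IL,CR}; motor: {CL,IL} vs {IR,CR};
#  outcome (both regions): {CL,CR} vs {IR,IL})
variable_class_of <- function(trial_type, variable) {
  stopifnot(variable %in% .VARIABLES)
  if (any(!trial_type %in% .TRIAL_TYPES))
    stop("aborted or unknown trial types have no task-variable class")
  one <- switch(variable,
    context = c("CL", "IR"),
    motor = c("CL", "IL"),
    post_decision_outcome = c("CL", "CR"),
    post_trial_outcome = c("CL", "CR"))
  ifelse(trial_type %in% one, 1L, 2L)
}

# Gaussian-bump kernel supported inside the variable's canonical window,
# normalized to peak 1; evaluated at bin starts (frames) of one trial.
draw_kernel <- function(variable, config) {
  win <- .KERNEL_WINDOWS[[variable]]
  tt <- (seq_len(config$trial_frames) - 1L) / config$frame_rate_hz
  width <- win[2] - win[1]
  center <- runif(1, win[1] + 0.1 * width, win[2] - 0.1 * width)
  k <- exp(-0.5 * ((tt - center) / (width / 5))^2)
  k[tt < win[1] | tt >= win[2]] <- 0
  k / max(k)
}

#' Ground-truth tuning with exponential amplitude decay and turnover
#'
#' Assigns each cell a tuning state per day. A fraction `prop_tuned` of cells
#' is tuned on day 1, each to one task variable with a random preferred class
#' and a log-normal day-1 amplitude. For a cell assigned on day `a`, the
#' amplitude on day `d >= a` is `amplitude * exp((a - d) / tau_v)`; cells
#' retained from day 1 therefore follow `amplitude_day1 * exp((1 - d) /
#' tau_v)` exactly. Each later day, every cell is re-assigned with
#' probability `turnover_prob` (tuning turnover: previously tuned cells may
#' lose or change tuning, untuned cells may gain it).
#'
#' @param config a [task_config()].
#' @param tau_by_variable named numeric vector of per-variable decay time
#'   constants in days (`Inf` allowed: no decay); names must cover
#'   `context`, `motor`, `post_decision_outcome`, `post_trial_outcome`.
#' @param seed integer seed.
#' @return A `ground_truth_tuning` list: matrices `amplitude` (cells x days,
#'   dF/F %, 0 when untuned), `variable` and `pref_class` (NA when untuned),
#'   `assigned_day`, logical `retained` (same tuning on all days as day 1),
#'   per-variable `kernels` (cells x trial_frames, peak 1), `baseline`
#'   (a.u.), and `tau_by_variable`.
#' @export
make_drifting_tuning <- function(config,
                                 tau_by_variable = c(
                                   context = 7.3, motor = 1.9,
                                   post_decision_outcome = 2.2,
                                   post_trial_outcome = 35.7),
                                 seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!all(.VARIABLES %in% names(tau_by_variable)))
    stop_config("tau_by_variable must name all four task variables")
  tau_by_variable <- tau_by_variable[.VARIABLES]
  if (any(is.na(tau_by_variable)) || any(tau_by_variable <= 0))
    stop_config("all tau values must be positive (Inf allowed)")

  with_seed(seed, {
    nc <- config$n_cells; nd <- config$n_days
    kernels <- lapply(.VARIABLES, function(v)
      t(vapply(seq_len(nc), function(i) draw_kernel(v, config),
               numeric(config$trial_frames))))
    names(kernels) <- .VARIABLES

    draw_state <- function() {
      if (runif(1) < config$prop_tuned)
        list(variable = sample(.VARIABLES, 1L),
             pref_class = sample(1:2, 1L),
             amplitude = rlnorm(1, config$amplitude_meanlog, config$amplitude_sdlog))
      else list(variable = NA_character_, pref_class = NA_integer_, amplitude = 0)
    }

    amplitude <- matrix(0, nc, nd)
    variable <- matrix(NA_character_, nc, nd)
    pref_class <- matrix(NA_integer_, nc, nd)
    assigned_day <- matrix(1L, nc, nd)

    for (i in seq_len(nc)) {
      st <- draw_state(); a_day <- 1L
      for (d in seq_len(nd)) {
        if (d > 1L && runif(1) < config$turnover_prob) {
          st <- draw_state(); a_day <- d
        }
        variable[i, d] <- st$variable
        pref_class[i, d] <- st$pref_class
        assigned_day[i, d] <- a_day
        if (!is.na(st$variable)) {
          tau <- tau_by_variable[[st$variable]]
          amplitude[i, d] <- st$amplitude *
            if (is.finite(tau)) exp((a_day - d) / tau) else 1
        }
      }
    }

    structure(list(
      amplitude = amplitude, variable = variable, pref_class = pref_class,
      assigned_day = assigned_day,
      retained = apply(assigned_day, 1L, function(r) all(r == 1L)),
      kernels = kernels,
      baseline = config$baseline_f * runif(nc, 0.9, 1.1),
      tau_by_variable = tau_by_variable
    ), class = "ground_truth_tuning")
  })
}

# normalized (sum = 1) single-exponential calcium impulse response
calcium_kernel <- function(config) {
  nk <- max(1L, ceiling(5 * config$calcium_tau_s * config$frame_rate_hz))
  k <- exp(-(seq_len(nk) - 1L) / (config$calcium_tau_s * config$frame_rate_hz))
  k / sum(k)
}

#' Forward model: one day's soma and neuropil fluorescence
#'
#' The neuropil is a shared, slow (low-pass filtered Gaussian) signal for
#' the whole field. Each cell's soma fluorescence is its baseline scaled by
#' tuned dF/F transients (amplitude x response kernel on preferred-class
#' trials, convolved with a single-exponential calcium kernel), plus
#' additive neuropil contamination with weight `neuropil_alpha_true` and
#' independent Gaussian noise of `noise_sd` dF/F percent.
#'
#' @param tuning a [make_drifting_tuning()] result.
#' @param trials a trial table from [generate_trial_schedule()].
#' @param config a [task_config()].
#' @param day day index (1-based) selecting the tuning state.
#' @param seed integer seed.
#' @return list with `f_soma` and `f_neuropil`, both cells x frames (a.u.).
#' @export
simulate_day_activity <- function(tuning, trials, config, day, seed = NULL) {
  stopifnot(inherits(tuning, "ground_truth_tuning"),
            inherits(config, "task_config"))
  if (nrow(tuning$amplitude) != config$n_cells)
    stop("tuning and config disagree on the number of cells")
  if (day < 1L || day > ncol(tuning$amplitude))
    stop("day outside the tuning's range")

  with_seed(seed, {
    n_frames <- max(trials$reward_end_frame) + 1L
    nc <- config$n_cells

    # shared slow neuropil signal: moving-average filtered white noise
    w <- ceiling(config$frame_rate_hz)  # ~1 s smoothing
    raw <- rnorm(n_frames + 2L * w)
    np <- as.numeric(stats::filter(raw, rep(1 / w, w), sides = 2L))
    np <- np[(w + 1L):(w + n_frames)]
    np <- 50 + config$neuropil_sd * np / max(sd(np), 1e-12)
    f_neuropil <- matrix(rep(np, each = nc), nrow = nc)

    live <- trials[trials$trial_type != "aborted", , drop = FALSE]
    ck <- calcium_kernel(config)

    f_soma <- matrix(0, nc, n_frames)
    for (i in seq_len(nc)) {
      resp <- numeric(n_frames)   # dF/F percent
      v <- tuning$variable[i, day]
      amp <- tuning$amplitude[i, day]
      if (!is.na(v) && amp > 0 && nrow(live) > 0L) {
        cls <- variable_class_of(live$trial_type, v)
        kern <- tuning$kernels[[v]][i, ]
        for (t in seq_len(nrow(live))) {
          if (cls[t] != tuning$pref_class[i, day]) next
          if (runif(1) >= config$event_prob) next
          jit <- if (config$amp_jitter_sdlog > 0)
            rlnorm(1, -config$amp_jitter_sdlog^2 / 2, config$amp_jitter_sdlog)
          else 1
          fr <- live$start_frame[t] + seq_along(kern)  # 1-based frame index
          resp[fr] <- resp[fr] + amp * jit * kern
        }
        resp <- convolve_causal(resp, ck)
      }
      base <- tuning$baseline[i]
      noise <- if (config$noise_sd > 0)
        rnorm(n_frames, 0, config$noise_sd / 100 * base) else 0
      f_soma[i, ] <- base * (1 + resp / 100) +
        config$neuropil_alpha_true * (np - mean(np)) + noise
    }
    list(f_soma = f_soma, f_neuropil = f_neuropil)
  })
}

# causal convolution truncated to the input length
convolve_causal <- function(x, k) {
  out <- stats::convolve(x, rev(k), type = "open")
  out[seq_along(x)]
}

# draw a square window from a field image
extract_patch <- function(field, cx, cy, size) {
  half <- size %/% 2L
  rows <- (cy - half):(cy - half + size - 1L)
  cols <- (cx - half):(cx - half + size - 1L)
  field[rows, cols]
}

# Smoothed-noise texture densely populated with background somata plus the
# tracked cells' blobs. The background constellation makes every window's
# surroundings distinctive, as in real cortical fields.
make_field <- function(centers, config, blob_sd = 3) {
  n <- config$field_px
  f <- matrix(rnorm(n * n), n, n)
  # separable moving-average smoothing for texture correlation
  sm <- function(m, w) {
    k <- rep(1 / w, w)
    m <- apply(m, 2L, function(col) as.numeric(stats::filter(col, k, sides = 2L, circular = TRUE)))
    t(apply(t(m), 2L, function(col) as.numeric(stats::filter(col, k, sides = 2L, circular = TRUE))))
  }
  f <- sm(f, 3L)
  f <- 0.3 + 0.08 * f / max(sd(f), 1e-12)
  xg <- matrix(seq_len(n), n, n, byrow = TRUE)
  yg <- matrix(seq_len(n), n, n)
  n_bg <- round(n * n / 150)    # ~6 background somata per 30 x 30 window
  bx <- runif(n_bg, 1, n); by <- runif(n_bg, 1, n)
  bamp <- runif(n_bg, 0.3, 0.8); bsd <- runif(n_bg, 1.5, 3.5)
  for (j in seq_len(n_bg)) {
    f <- f + bamp[j] * exp(-((xg - bx[j])^2 + (yg - by[j])^2) / (2 * bsd[j]^2))
  }
  for (i in seq_len(nrow(centers)))
    f <- f + blob_image(xg, yg, centers[i, 1], centers[i, 2],
                        attr(centers, "shapes")[i, ])
  f
}

# elliptical Gaussian soma blob; shape = (amp, sx, sy, theta)
blob_image <- function(xg, yg, cx, cy, shape) {
  ct <- cos(shape[["theta"]]); st <- sin(shape[["theta"]])
  dx <- xg - cx; dy <- yg - cy
  u <- ct * dx + st * dy; v <- -st * dx + ct * dy
  shape[["amp"]] * exp(-0.5 * ((u / shape[["sx"]])^2 + (v / shape[["sy"]])^2))
}

draw_blob_shapes <- function(n) {
  cbind(amp = runif(n, 0.55, 0.85), sx = runif(n, 2, 4.5),
        sy = runif(n, 2, 4.5), theta = runif(n, 0, pi))
}

#' Per-day ROI image patches with controllable morphological stability
#'
#' Builds a synthetic imaging field per day (textured background plus a
#' Gaussian soma blob per cell) and cuts a square window centered on each
#' ROI. Stable cells keep their field location across days up to small
#' pixel jitter and additive noise; `n_unstable` randomly chosen cells are
#' relocated to a different field position on days 2 and later, emulating
#' lost or mismatched ROIs.
#'
#' @param config a [task_config()].
#' @param n_unstable number of cells whose patch moves on later days.
#' @param seed integer seed.
#' @param jitter_px maximum per-day absolute re-centering jitter in pixels
#'   for stable cells.
#' @param patch_noise_sd additive pixel noise s.d. on later days (field
#'   intensity units; the blob has amplitude ~0.7).
#' @return list with `patches` (per-day list of cells x H x W arrays),
#'   `fields` (per-day field images), `centers` (per-day cell centers),
#'   `unstable_ids`, and `patch_px`.
#' @export
generate_roi_patches <- function(config, n_unstable = 0L, seed = NULL,
                                 jitter_px = 1L, patch_noise_sd = 0.05) {
  stopifnot(inherits(config, "task_config"))
  if (n_unstable > config$n_cells)
    stop("n_unstable exceeds the number of cells")
  with_seed(seed, {
    nc <- config$n_cells; size <- config$patch_px
    margin <- size  # keep windows and jitter inside the field
    lo <- margin + 1L; hi <- config$field_px - margin
    centers1 <- cbind(x = sample(lo:hi, nc, replace = TRUE),
                      y = sample(lo:hi, nc, replace = TRUE))
    shapes1 <- draw_blob_shapes(nc)
    attr(centers1, "shapes") <- shapes1
    unstable_ids <- if (n_unstable > 0L) sort(sample(nc, n_unstable)) else integer(0)

    # relocation targets: a distant random field location (lost/mismatched
    # ROI), fixed once for all later days
    reloc_centers <- centers1
    for (i in unstable_ids) {
      repeat {
        cand <- c(sample(lo:hi, 1L), sample(lo:hi, 1L))
        if (sum((cand - centers1[i, ])^2) >= (2L * size)^2) break
      }
      reloc_centers[i, ] <- cand
    }

    field1 <- make_field(centers1, config)
    fields <- vector("list", config$n_days)
    centers <- vector("list", config$n_days)
    patches <- vector("list", config$n_days)
    fields[[1L]] <- field1
    centers[[1L]] <- centers1

    cut_all <- function(field, ctr) {
      arr <- array(0, dim = c(nc, size, size))
      for (i in seq_len(nc)) arr[i, , ] <- extract_patch(field, ctr[i, 1], ctr[i, 2], size)
      arr
    }
    patches[[1L]] <- cut_all(field1, centers1)

    for (d in seq_len(config$n_days)[-1L]) {
      ctr <- reloc_centers
      # later days keep the day-1 field; unstable cells' windows move
      fld <- field1
      if (patch_noise_sd > 0)
        fld <- fld + matrix(rnorm(length(fld), 0, patch_noise_sd),
                            nrow(fld), ncol(fld))
      if (jitter_px > 0L) {
        jx <- sample(seq(-jitter_px, jitter_px), nc, replace = TRUE)
        jy <- sample(seq(-jitter_px, jitter_px), nc, replace = TRUE)
        ctr_j <- cbind(ctr[, 1] + jx, ctr[, 2] + jy)
      } else ctr_j <- ctr
      fields[[d]] <- fld
      centers[[d]] <- ctr_j
      patches[[d]] <- cut_all(fld, ctr_j)
    }

    list(patches = patches, fields = fields, centers = centers,
         unstable_ids = unstable_ids, patch_px = size)
  })
}

#' Random null windows from a field image
#'
#' Samples square windows at uniformly random positions at least one window
#' width away from `exclude_center`, for the ROI-stability null
#' distribution.
#'
#' @param field a field image matrix.
#' @param size window side in pixels.
#' @param n number of windows.
#' @param exclude_center `c(x, y)` center to avoid, or `NULL`.
#' @param seed integer seed.
#' @return list of `n` size x size matrices.
#' @export
sample_null_windows <- function(field, size, n = 100L, exclude_center = NULL,
                                seed = NULL) {
  with_seed(seed, {
    half <- size %/% 2L
    lo <- half + 1L
    hix <- ncol(field) - (size - half) ; hiy <- nrow(field) - (size - half)
    out <- vector("list", n)
    got <- 0L
    while (got < n) {
      cx <- sample(lo:hix, 1L); cy <- sample(lo:hiy, 1L)
      if (!is.null(exclude_center) &&
          sum((c(cx, cy) - exclude_center)^2) < size^2) next
      got <- got + 1L
      out[[got]] <- extract_patch(field, cx, cy, size)
    }
    out
  })
}

#' Generate a complete multi-day synthetic experiment
#'
#' Composes the trial-schedule, tuning, activity and ROI-patch generators
#' into one experiment bundle with ground truth attached. Deterministic
#' given `(config, tau_by_variable, seed)`.
#'
#' @param config a [task_config()].
#' @param tau_by_variable per-variable decay constants (days), see
#'   [make_drifting_tuning()].
#' @param seed integer master seed for this experiment.
#' @param mouse_id,experiment_id identifiers carried in `meta`.
#' @param n_unstable number of morphologically unstable cells.
#' @return An `experiment_bundle`: `days` (per-day list of `f_soma`,
#'   `f_neuropil`, `trials`, `roi_patches`), `roi` (fields/centers for null
#'   windows), `ground_truth`, and `meta`.
#' @export
generate_experiment <- function(config,
                                tau_by_variable = c(
                                  context = 7.3, motor = 1.9,
                                  post_decision_outcome = 2.2,
                                  post_trial_outcome = 35.7),
                                seed = 1L,
                                mouse_id = "m1", experiment_id = "e1",
                                n_unstable = 0L) {
  stopifnot(inherits(config, "task_config"))
  tuning <- make_drifting_tuning(config, tau_by_variable,
                                 seed = derive_seed(seed, "tuning"))
  roi <- generate_roi_patches(config, n_unstable = n_unstable,
                              seed = derive_seed(seed, "roi"))
  days <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    trials <- generate_trial_schedule(config,
                                      seed = derive_seed(seed, paste0("sched", d)))
    act <- simulate_day_activity(tuning, trials, config, day = d,
                                 seed = derive_seed(seed, paste0("act", d)))
    days[[d]] <- list(f_soma = act$f_soma, f_neuropil = act$f_neuropil,
                      trials = trials, roi_patches = roi$patches[[d]])
  }
  structure(list(
    days = days,
    roi = roi,
    ground_truth = tuning,
    meta = list(mouse_id = mouse_id, experiment_id = experiment_id,
                frame_rate_hz = config$frame_rate_hz, seed = seed),
    config = config
  ), class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("experiment_bundle %s/%s: %d cells, %d days, %d trials/day\n",
              x$meta$mouse_id, x$meta$experiment_id,
              x$config$n_cells, length(x$days), x$config$n_trials))
  invisible(x)
}
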