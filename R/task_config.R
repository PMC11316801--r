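#' Task and simulation configuration
#'
#' Builds the configuration object shared by the synthetic experiment
#' generator and the analysis pipeline. Defaults reproduce the virtual
#' T-maze conditions the pipeline assumes: 10 Hz imaging, 3 s maze-start to
#' decision, 3 s decision to maze end, 3 s post-trial screen (90 frames per
#' trial), four trial types (CL, IR, IL, CR), and ~74% correct behavior.
#'
#' @param frame_rate_hz imaging frame rate, frames/s.
#' @param pre_decision_s,post_decision_s,post_trial_s trial segment durations
#'   in seconds (start to decision, decision to trial end, post-trial screen).
#' @param n_trials trials per session.
#' @param n_days number of consecutive imaging days.
#' @param target_performance probability the simulated agent chooses the
#'   rewarded side, in `[0.5, 1]`.
#' @param abort_rate probability a trial is aborted (no decision); aborted
#'   trials are excluded from every analysis.
#' @param anti_repeat_span trials over which the context repeat probability
#'   ramps from 50% to 0%.
#' @param bias_window trailing window (trials) for the response-bias gate:
#'   when one side exceeds double the other within the window, the context
#'   rewarding the non-preferred side is shown until the bias clears.
#' @param n_cells number of simultaneously imaged cells.
#' @param noise_sd independent per-frame noise, dF/F percent.
#' @param neuropil_alpha_true contamination weight used by the forward model,
#'   in `[0, 1]`.
#' @param neuropil_sd standard deviation of the shared neuropil signal (a.u.).
#' @param baseline_f mean baseline fluorescence per cell (a.u.).
#' @param prop_tuned fraction of cells tuned to some task variable on day 1.
#' @param amplitude_meanlog,amplitude_sdlog log-normal parameters of day-1
#'   tuning amplitudes (dF/F percent).
#' @param event_prob probability a tuned cell emits its transient on a
#'   preferred-class trial (trial-to-trial reliability).
#' @param amp_jitter_sdlog log-normal sd of multiplicative trial-to-trial
#'   amplitude jitter (mean 1); 0 disables jitter.
#' @param turnover_prob per-day probability that a cell's tuning is
#'   re-assigned (tuning turnover).
#' @param calcium_tau_s decay time constant of the calcium impulse response,
#'   seconds (GCaMP6s-like).
#' @param patch_px side of the square ROI patch in pixels (30 px = 30 um at
#'   1 um/px).
#' @param field_px side of the synthetic imaging field in pixels.
#'
#' @return A `task_config` list with validated fields.
#' @export
task_config <- function(frame_rate_hz = 10,
                        pre_decision_s = 3, post_decision_s = 3, post_trial_s = 3,
                        n_trials = 60L,
                        n_days = 5L,
                        target_performance = 0.74,
                        abort_rate = 0.02,
                        anti_repeat_span = 10L,
                        bias_window = 10L,
                        n_cells = 100L,
                        noise_sd = 15,
                        neuropil_alpha_true = 0.7,
                        neuropil_sd = 8,
                        baseline_f = 100,
                        prop_tuned = 0.6,
                        amplitude_meanlog = log(30), amplitude_sdlog = 0.4,
                        event_prob = 0.8,
                        amp_jitter_sdlog = 0.25,
                        turnover_prob = 0.1,
                        calcium_tau_s = 0.7,
                        patch_px = 30L,
                        field_px = 200L) {
  cfg <- list(
    frame_rate_hz = frame_rate_hz,
    pre_decision_s = pre_decision_s, post_decision_s = post_decision_s,
    post_trial_s = post_trial_s,
    n_trials = as.integer(n_trials), n_days = as.integer(n_days),
    target_performance = target_performance, abort_rate = abort_rate,
    anti_repeat_span = as.integer(anti_repeat_span),
    bias_window = as.integer(bias_window),
    n_cells = as.integer(n_cells), noise_sd = noise_sd,
    neuropil_alpha_true = neuropil_alpha_true, neuropil_sd = neuropil_sd,
    baseline_f = baseline_f, prop_tuned = prop_tuned,
    amplitude_meanlog = amplitude_meanlog, amplitude_sdlog = amplitude_sdlog,
    event_prob = event_prob, amp_jitter_sdlog = amp_jitter_sdlog,
    turnover_prob = turnover_prob,
    calcium_tau_s = calcium_tau_s,
    patch_px = as.integer(patch_px), field_px = as.integer(field_px)
  )
  validate_task_config(cfg)
}

validate_task_config <- function(cfg) {
  num <- unlist(cfg[c("frame_rate_hz", "pre_decision_s", "post_decision_s",
                      "post_trial_s", "n_trials", "n_days", "n_cells",
                      "anti_repeat_span", "bias_window", "baseline_f",
                      "calcium_tau_s", "patch_px", "field_px")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop_config("all durations and counts must be finite and strictly positive")
  if (!is.finite(cfg$target_performance) ||
      cfg$target_performance < 0.5 || cfg$target_performance > 1)
    stop_config("target_performance must lie in [0.5, 1]")
  if (cfg$abort_rate < 0 || cfg$abort_rate >= 1)
    stop_config("abort_rate must lie in [0, 1)")
  if (cfg$neuropil_alpha_true < 0 || cfg$neuropil_alpha_true > 1)
    stop_config("neuropil_alpha_true must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$neuropil_sd < 0)
    stop_config("noise standard deviations must be non-negative")
  if (cfg$patch_px < 8L)
    stop_config("patch_px must be at least 8 pixels")
  tf <- cfg$frame_rate_hz *
    (cfg$pre_decision_s + cfg$post_decision_s + cfg$post_trial_s)
  if (abs(tf - round(tf)) > 1e-9)
    stop_config("trial length in frames must be integral")
  cfg$trial_frames <- as.integer(round(tf))
  cfg$decision_frame_offset <- as.integer(round(cfg$frame_rate_hz * cfg$pre_decision_s))
  cfg$end_frame_offset <- as.integer(round(cfg$frame_rate_hz *
                                             (cfg$pre_decision_s + cfg$post_decision_s)))
  class(cfg) <- "task_config"
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "task_config: %d cells, %d trials/day x %d days @ %g Hz (%d frames/trial)\n",
    x$n_cells, x$n_trials, x$n_days, x$frame_rate_hz, x$trial_frames))
  cat(sprintf("  target performance %.2f, abort rate %.2f, alpha_true %.2f\n",
              x$target_performance, x$abort_rate, x$neuropil_alpha_true))
  invisible(x)
}

# deterministic (context, choice) -> trial type mapping
trial_type_of <- function(context, choice) {
  ifelse(choice == "none", "aborted",
    ifelse(context == 1L,
      ifelse(choice == "left", "CL", "IR"),
      ifelse(choice == "left", "IL", "CR")))
}
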