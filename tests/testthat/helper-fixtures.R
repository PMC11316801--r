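# shared fixtures built in code

# tiny config for fast end-to-end paths
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_cells = 12L, n_trials = 40L, n_days = 3L)
  defaults[names(args)] <- args
  do.call(task_config, defaults)
}

# trial tensor with a prescribed class signal: cells x trials x bins array
# where `signal_cells` carry `amp` extra dF/F on class-1 trials inside
# `signal_bins`; labels alternate over the four trial types
make_labeled_tensor <- function(n_cells = 10L, trials_per_type = 10L,
                                n_bins = 90L, signal_cells = integer(0),
                                variable = "context", amp = 0,
                                signal_bins = seq_len(n_bins), noise_sd = 1,
                                seed = 1L) {
  set.seed(seed)
  types <- rep(c("CL", "IR", "IL", "CR"), each = trials_per_type)
  types <- sample(types)
  nt <- length(types)
  x <- array(rnorm(n_cells * nt * n_bins, sd = noise_sd),
             dim = c(n_cells, nt, n_bins))
  if (length(signal_cells) && amp != 0) {
    cls <- variable_labels(types, variable)
    for (i in signal_cells)
      x[i, cls == 1L, signal_bins] <- x[i, cls == 1L, signal_bins] + amp
  }
  structure(x, labels = types, bin_duration_s = 0.1, window = c(0, n_bins / 10),
            class = c("trial_tensor", "array"))
}

# trial table from explicit per-type counts (frames laid out contiguously)
trials_from_counts <- function(n_CL, n_IR, n_IL, n_CR, n_aborted = 0L) {
  tt <- c(rep("CL", n_CL), rep("IR", n_IR), rep("IL", n_IL), rep("CR", n_CR),
          rep("aborted", n_aborted))
  n <- length(tt)
  start <- (seq_len(n) - 1L) * 90L
  data.frame(
    index = seq_len(n) - 1L,
    context = ifelse(tt %in% c("CL", "IR"), 1L, 2L),
    choice = ifelse(tt == "aborted", "none",
                    ifelse(tt %in% c("CL", "IL"), "left", "right")),
    outcome = ifelse(tt == "aborted", "aborted",
                     ifelse(tt %in% c("CL", "CR"), "correct", "incorrect")),
    trial_type = tt,
    start_frame = start, decision_frame = start + 30L,
    end_frame = start + 60L, reward_end_frame = start + 89L,
    stringsAsFactors = FALSE)
}

# run a small python oracle script; fails the calling test on error
run_python_oracle <- function(code) {
  res <- suppressWarnings(system2("python", c("-"), input = code,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed: ", paste(res, collapse = "\n"))
  res
}
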