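#' Estimate the neuropil contamination weight
#'
#' Returns the weight `alpha` in `[0, 1]` minimizing the absolute Pearson
#' correlation between the corrected trace
#' `f_soma - alpha * (f_neuropil - mean(f_neuropil))` and the neuropil
#' trace, at grid resolution 0.001. The correlation is evaluated in closed
#' form on the full grid (it is a smooth rational function of `alpha`), so
#' the result equals an exhaustive grid search. An undefined correlation
#' (zero-variance corrected trace) is treated as 0.
#'
#' @param f_soma_trace,f_neuropil_trace equal-length numeric traces (a.u.),
#'   at least 100 frames.
#' @return `alpha`, with attribute `warning_flag = TRUE` when the neuropil
#'   has zero variance (correction is a no-op and alpha = 0).
#' @export
estimate_alpha <- function(f_soma_trace, f_neuropil_trace) {
  if (length(f_soma_trace) != length(f_neuropil_trace))
    stop("soma and neuropil traces must have equal length")
  if (length(f_soma_trace) < 100L)
    stop("need at least 100 frames to estimate alpha")
  if (any(!is.finite(f_soma_trace)) || any(!is.finite(f_neuropil_trace)))
    stop("traces must be finite")

  npd <- f_neuropil_trace - mean(f_neuropil_trace)
  v_n <- sum(npd^2)
  if (v_n == 0) return(structure(0, warning_flag = TRUE))

  sd_ <- f_soma_trace - mean(f_soma_trace)
  c_sn <- sum(sd_ * npd)
  v_s <- sum(sd_^2)

  grid <- seq(0, 1, by = 0.001)
  num <- c_sn - grid * v_n                      # cov(f_corr, f_np) * (n-1)
  den <- sqrt(pmax(v_s - 2 * grid * c_sn + grid^2 * v_n, 0) * v_n)
  ac <- ifelse(den == 0, 0, abs(num / den))    # undefined correlation -> 0
  grid[which.min(ac)]
}

#' Neuropil-correct a soma trace
#'
#' `f_corrected(n) = f_soma(n) - alpha * (f_neuropil(n) - mean(f_neuropil))`.
#'
#' @param f_soma_trace,f_neuropil_trace equal-length numeric traces (a.u.).
#' @param alpha contamination weight in `[0, 1]`.
#' @param neuropil_mean time-averaged neuropil fluorescence; defaults to
#'   `mean(f_neuropil_trace)`.
#' @return corrected trace (a.u.).
#' @export
neuropil_correct <- function(f_soma_trace, f_neuropil_trace, alpha,
                             neuropil_mean = mean(f_neuropil_trace)) {
  if (length(f_soma_trace) != length(f_neuropil_trace))
    stop("soma and neuropil traces must have equal length")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  f_soma_trace - alpha * (f_neuropil_trace - neuropil_mean)
}

#' Baseline fluorescence as the mode of the trace's density
#'
#' F0 is the arg-max of a Gaussian kernel density estimate of the corrected
#' fluorescence distribution over the entire time series (Silverman
#' bandwidth, 512 evaluation points spanning the data range). A histogram
#' mode estimator is available for sensitivity checks.
#'
#' @param corrected_trace numeric trace (a.u.), at least 100 frames.
#' @param method `"kde"` (default) or `"hist"` (mode of a 100-bin histogram).
#' @return F0 (a.u.); errors if the estimated mode is not positive.
#' @export
estimate_f0 <- function(corrected_trace, method = c("kde", "hist")) {
  method <- match.arg(method)
  if (length(corrected_trace) < 100L) stop("need at least 100 frames")
  if (any(!is.finite(corrected_trace))) stop("trace must be finite")
  if (diff(range(corrected_trace)) == 0) {
    f0 <- corrected_trace[1]
  } else if (method == "kde") {
    d <- density(corrected_trace, bw = "nrd0", n = 512,
                 from = min(corrected_trace), to = max(corrected_trace))
    f0 <- d$x[which.max(d$y)]
  } else {
    h <- graphics::hist(corrected_trace, breaks = 100, plot = FALSE)
    f0 <- h$mids[which.max(h$counts)]
  }
  if (f0 <= 0) stop("estimated F0 is not positive; dF/F undefined")
  f0
}

#' Percent fluorescence change
#'
#' `dF/F(%) = 100 * (F - F0) / F0`, elementwise.
#'
#' @param corrected_trace numeric trace (a.u.).
#' @param f0 baseline fluorescence, must be positive.
#' @return dF/F in percent.
#' @export
compute_dff <- function(corrected_trace, f0) {
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be positive")
  100 * (corrected_trace - f0) / f0
}

#' Trial-align dF/F traces into a cells x trials x bins tensor
#'
#' Bin `b` of trial `t` is `dff[start_frame(t) + b]` (0-based frames);
#' aborted trials are dropped. With the default 9-s window at 10 Hz the
#' tensor has 90 bins, with trial start at bin 1, the decision point at bin
#' 31 and trial end at bin 61 (1-based).
#'
#' @param dff cells x frames matrix of dF/F (%), or a single trace.
#' @param trials trial table with 0-based `start_frame` and `trial_type`.
#' @param window half-open window in seconds from trial start.
#' @param frame_rate_hz frames per second.
#' @return A `trial_tensor`: array cells x trials x bins with attributes
#'   `labels` (trial types), `bin_duration_s` and `window`.
#' @export
align_to_trials <- function(dff, trials, window = c(0, 9),
                            frame_rate_hz = 10) {
  if (is.null(dim(dff))) dff <- matrix(dff, nrow = 1L)
  keep <- trials$trial_type != "aborted"
  tr <- trials[keep, , drop = FALSE]
  n_bins <- as.integer(round((window[2] - window[1]) * frame_rate_hz))
  off0 <- as.integer(round(window[1] * frame_rate_hz))
  n_frames <- ncol(dff)
  tens <- array(NA_real_, dim = c(nrow(dff), nrow(tr), n_bins))
  for (t in seq_len(nrow(tr))) {
    fr <- tr$start_frame[t] + off0 + seq_len(n_bins)  # 1-based columns
    if (max(fr) > n_frames || min(fr) < 1L)
      stop(sprintf("window exceeds the recording for trial index %d",
                   tr$index[t]))
    tens[, t, ] <- dff[, fr, drop = FALSE]
  }
  structure(tens, labels = tr$trial_type, bin_duration_s = 1 / frame_rate_hz,
            window = window, class = c("trial_tensor", "array"))
}

#' Preprocess one experiment bundle into per-day trial tensors
#'
#' Runs the neuropil correction (with per-cell alpha estimation), dF/F
#' conversion and trial alignment on every day of a bundle.
#'
#' @param bundle an `experiment_bundle`.
#' @param window alignment window in seconds from trial start.
#' @return list with per-day `tensors` (see [align_to_trials()]) and
#'   `alpha` (cells x days matrix of estimated contamination weights).
#' @export
preprocess_bundle <- function(bundle, window = c(0, 9)) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  nd <- length(bundle$days)
  nc <- nrow(bundle$days[[1]]$f_soma)
  alpha <- matrix(NA_real_, nc, nd)
  tensors <- vector("list", nd)
  for (d in seq_len(nd)) {
    day <- bundle$days[[d]]
    dff <- matrix(NA_real_, nc, ncol(day$f_soma))
    for (i in seq_len(nc)) {
      a <- estimate_alpha(day$f_soma[i, ], day$f_neuropil[i, ])
      corr <- neuropil_correct(day$f_soma[i, ], day$f_neuropil[i, ], a)
      dff[i, ] <- compute_dff(corr, estimate_f0(corr))
      alpha[i, d] <- a
    }
    tensors[[d]] <- align_to_trials(dff, day$trials, window,
                                    bundle$config$frame_rate_hz)
  }
  list(tensors = tensors, alpha = alpha)
}
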