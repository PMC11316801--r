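#' Integrate decoding performance above chance over a window
#'
#' Trapezoidal integral of `mean_performance - 0.5` over the variable's
#' window (endpoints inclusive, so a constant curve at 1.0 over a 1.5-s
#' window integrates to exactly 0.75 fraction-seconds). The integral is
#' signed: dips below chance subtract. Set `clip = TRUE` to clip the curve
#' at chance first.
#'
#' @param curve a `decoding_curve`.
#' @param window `c(t0, t1)` seconds from trial start; defaults to the
#'   curve's variable's canonical 1.5-s window.
#' @param clip clip performance at chance before integrating.
#' @return area in fraction-seconds.
#' @export
integrate_window <- function(curve, window = NULL, clip = FALSE) {
  if (is.null(window)) window <- .VARIABLE_WINDOWS[[curve$variable]]
  tt <- curve$bin_time_s
  keep <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  if (length(keep) < 2L)
    stop("window outside the extent of the decoded bins")
  if (min(tt[keep]) > window[1] + 1e-9 || max(tt[keep]) < window[2] - 1e-9)
    stop("window outside the extent of the decoded bins")
  y <- curve$mean_performance[keep] - 0.5
  if (clip) y <- pmax(y, 0)
  x <- tt[keep]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Normalize window-integrated performance by the train day
#'
#' `NP(d) = area(d) / area(train_day)`; NP equals 1 on the train day by
#' construction and 0 at chance-level decoding. A series whose train-day
#' area is not positive cannot be normalized and is flagged.
#'
#' @param areas numeric vector of window integrals named or ordered by day.
#' @param days day numbers matching `areas`.
#' @param train_day reference day (default 1).
#' @return list: `np` (per day), `days`, `excluded` flag.
#' @export
normalize_performance <- function(areas, days = seq_along(areas),
                                  train_day = 1L) {
  i0 <- which(days == train_day)
  if (!length(i0)) stop("train day missing from the series")
  a1 <- areas[i0[1]]
  if (!is.finite(a1) || a1 <= 0)
    return(list(np = rep(NA_real_, length(areas)), days = days,
                excluded = TRUE))
  list(np = areas / a1, days = days, excluded = FALSE)
}

#' Fit an exponential decay across days
#'
#' Variants: `cc_decay` fits `y = A * exp((1 - day) / tau)` (single-cell
#' correlation decay); `perf_baseline` fits `y = A * exp((1 - day) / tau) +
#' 0.5`, the 0.5 accounting for the chance-level baseline of decoding
#' performance; `normalized` fits `y = exp((1 - day) / tau)` with tau the
#' only free parameter, so the fitted curve is exactly 1 on day 1 and falls
#' to `1/e` (~37%) of that value at `day = 1 + tau`. Nonlinear least
#' squares with tau in (0.05, 100], A in [0, 2], multistart from tau in
#' {0.5, 2, 8, 32}.
#'
#' @param values observed series.
#' @param days day numbers.
#' @param variant one of `cc_decay`, `perf_baseline`, `normalized`.
#' @return a `decay_fit` list: `variant`, `amplitude` (NA for
#'   `normalized`), `tau`, `sse`, `r2` (relative to the mean-only model),
#'   `n_points`, `converged`.
#' @export
fit_decay <- function(values, days,
                      variant = c("cc_decay", "perf_baseline", "normalized")) {
  variant <- match.arg(variant)
  ok <- is.finite(values) & is.finite(days)
  values <- values[ok]; days <- days[ok]
  need <- if (variant == "normalized") 2L else 3L
  if (length(values) < need)
    stop(sprintf("variant %s needs at least %d day-points", variant, need))
  offset <- if (variant == "perf_baseline") 0.5 else 0
  free_amp <- variant != "normalized"

  pred <- function(tau, A) A * exp((1 - days) / tau) + offset
  sse_of <- function(tau, A) sum((values - pred(tau, A))^2)

  tau_lo <- 0.05 + 1e-9; tau_hi <- 100
  starts <- c(0.5, 2, 8, 32)
  best <- NULL
  if (!free_amp) {
    # 1-D: coarse log-grid then golden-section refinement
    grid <- exp(seq(log(tau_lo), log(tau_hi), length.out = 200L))
    g_sse <- vapply(grid, sse_of, numeric(1), A = 1)
    i <- which.min(g_sse)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(function(t) sse_of(t, 1), c(lo, hi), tol = 1e-10)
    best <- list(tau = opt$minimum, A = NA_real_, sse = opt$objective,
                 converged = TRUE)
  } else {
    a0 <- max(min(max(values - offset), 2), 0.01)
    for (t0 in starts) {
      o <- tryCatch(
        optim(c(t0, a0), function(p) sse_of(p[1], p[2]),
              method = "L-BFGS-B", lower = c(tau_lo, 0),
              upper = c(tau_hi, 2), control = list(factr = 1e4)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$sse)
        best <- list(tau = o$par[1], A = o$par[2], sse = o$value,
                     converged = o$convergence == 0L)
    }
    if (is.null(best))
      return(structure(list(variant = variant, amplitude = NA_real_,
                            tau = NA_real_, sse = NA_real_, r2 = NA_real_,
                            n_points = length(values), converged = FALSE),
                       class = "decay_fit"))
  }
  sst <- sum((values - mean(values))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else if (best$sse < 1e-12) 1 else -Inf
  structure(list(variant = variant, amplitude = best$A, tau = best$tau,
                 sse = best$sse, r2 = r2, n_points = length(values),
                 converged = best$converged),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit (%s): tau = %.3g days, A = %s, SSE = %.3g, R2 = %.3g\n",
              x$variant, x$tau,
              if (is.na(x$amplitude)) "-" else sprintf("%.3g", x$amplitude),
              x$sse, x$r2))
  invisible(x)
}

#' Filter decay fits by goodness of fit
#'
#' Keeps fits with SSE at most 1.6 and positive R-squared (better than a
#' horizontal line through the mean). Note the SSE cutoff is tied to the
#' scale of the fitted quantity.
#'
#' @param fits list of `decay_fit`s or a data.frame with `sse` and `r2`.
#' @param sse_max SSE threshold.
#' @return the retained subset (same container type).
#' @export
filter_fits <- function(fits, sse_max = 1.6) {
  if (is.data.frame(fits)) {
    keep <- is.finite(fits$sse) & fits$sse <= sse_max &
      is.finite(fits$r2) & fits$r2 > 0
    return(fits[keep, , drop = FALSE])
  }
  Filter(function(f) is.finite(f$sse) && f$sse <= sse_max &&
           is.finite(f$r2) && f$r2 > 0, fits)
}

#' Rankit (inverse-normal) transform
#'
#' `transformed = qnorm((rank - 0.5) / n)` with ties receiving averaged
#' ranks; used to normalize skewed fit parameters before mixed-effects
#' comparisons. Monotone in the input; the median of an odd-length
#' tie-free sample maps to 0.
#'
#' @param values finite numeric vector, length at least 2.
#' @return list: `values`, `ranks`, `n`, `transformed`.
#' @export
rankit <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  r <- rank(values, ties.method = "average")
  n <- length(values)
  list(values = values, ranks = r, n = n,
       transformed = qnorm((r - 0.5) / n))
}

#' Linear mixed-effects comparison with mouse and experiment intercepts
#'
#' Fits `response ~ fixed effect + (1 | mouse) + (1 | experiment)` by REML
#' and reports pairwise two-sided Wald F-tests between fixed-effect levels
#' (each pair refit on its two-level subset), with p-values floored at
#' 1e-5. A singular random-effects structure is refit without the
#' offending term and flagged.
#'
#' @param values response (typically rankit-transformed upstream).
#' @param group fixed-effect labels (task variable or trial type).
#' @param mouse,experiment random-effect grouping ids (nominal).
#' @return list: `pairwise` data.frame (`level_a`, `level_b`, `estimate`,
#'   `F`, `p`), `model` (full lme4 fit or `NULL`), `singular_flag`.
#' @export
lme_compare <- function(values, group, mouse, experiment) {
  dat <- data.frame(y = values, g = factor(group),
                    mouse = factor(mouse), experiment = factor(experiment))
  if (nlevels(dat$g) < 2L) stop("need at least 2 fixed-effect levels")

  fit_one <- function(d) {
    # progressively simpler structures when the RE structure is singular
    forms <- list(y ~ g + (1 | mouse) + (1 | experiment),
                  y ~ g + (1 | mouse),
                  y ~ g + (1 | experiment))
    for (fi in seq_along(forms)) {
      m <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(forms[[fi]], data = d, REML = TRUE))),
        error = function(e) NULL)
      if (!is.null(m) && !lme4::isSingular(m, tol = 1e-5))
        return(list(model = m, singular = fi > 1L, lm = FALSE))
    }
    list(model = stats::lm(y ~ g, data = d), singular = TRUE, lm = TRUE)
  }

  lv <- levels(dat$g)
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    d <- droplevels(dat[dat$g %in% pr, , drop = FALSE])
    f <- fit_one(d)
    if (f$lm) {
      cf <- summary(f$model)$coefficients
      est <- cf[2L, 1L]; Fv <- cf[2L, 3L]^2
      df2 <- f$model$df.residual
    } else {
      cf <- summary(f$model)$coefficients
      est <- cf[2L, "Estimate"]
      Fv <- (cf[2L, "Estimate"] / cf[2L, "Std. Error"])^2
      df2 <- nrow(d) - nrow(cf)
    }
    p <- pf(Fv, 1, max(df2, 1), lower.tail = FALSE)
    data.frame(level_a = pr[1], level_b = pr[2], estimate = est, F = Fv,
               p = max(p, 1e-5), singular = f$singular)
  })
  full <- fit_one(dat)
  list(pairwise = do.call(rbind, rows),
       model = if (full$lm) NULL else full$model,
       singular_flag = full$singular)
}
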