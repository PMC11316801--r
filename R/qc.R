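#' Behavioral session-inclusion gate
#'
#' A session is analyzable when it has at least 2 trials of each of the four
#' trial types (CL, IR, IL, CR) and overall performance above chance
#' (fraction correct > 0.5). Aborted trials are ignored.
#'
#' @param trials trial table with a `trial_type` column.
#' @return list: per-type counts `n_CL`, `n_IR`, `n_IL`, `n_CR`,
#'   `min_count`, `performance` and the `included` flag.
#' @export
check_session_inclusion <- function(trials) {
  tt <- trials$trial_type[trials$trial_type != "aborted"]
  if (!length(tt)) stop("session has no non-aborted trials")
  n <- vapply(.TRIAL_TYPES, function(x) sum(tt == x), integer(1))
  performance <- (n[["CL"]] + n[["CR"]]) / sum(n)
  min_count <- min(n)
  list(n_CL = n[["CL"]], n_IR = n[["IR"]], n_IL = n[["IL"]], n_CR = n[["CR"]],
       min_count = min_count, performance = performance,
       included = min_count >= 2L && performance > 0.5)
}

# precomputed rotations of 1..n (rotation s moves entry s+1 to the front)
.rotations <- function(n) lapply(seq_len(n - 1L), function(s) c((s + 1L):n, seq_len(s)))

#' Activity-reliability test for one cell-day
#'
#' Pearson correlation between the mean response over odd correct trials and
#' over even correct trials, compared with a null in which every trial's bin
#' series is circularly shifted by an independent uniform random offset
#' before re-computing the odd/even correlation (100 iterations). The cell
#' is reliable when the true correlation exceeds the null's 95th percentile.
#'
#' @param cell_mat trials x bins matrix of dF/F for correct trials only.
#' @param n_iter number of circular-shuffle iterations.
#' @param seed integer seed.
#' @return list: `cc_true`, `null_ccs`, `threshold` (95th percentile),
#'   `reliable`, and `degenerate` (TRUE when the correlation was undefined).
#' @export
reliability_test <- function(cell_mat, n_iter = 100L, seed = NULL) {
  if (nrow(cell_mat) < 4L) stop("need at least 4 correct trials")
  nt <- nrow(cell_mat); nb <- ncol(cell_mat)
  oi <- odd_idx(nt); ei <- even_idx(nt)
  cc_true <- safe_cor(colMeans(cell_mat[oi, , drop = FALSE]),
                      colMeans(cell_mat[ei, , drop = FALSE]))
  rot <- .rotations(nb)
  null_ccs <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      s <- sample.int(nb - 1L, nt, replace = TRUE)
      sh <- cell_mat
      for (t in seq_len(nt)) sh[t, ] <- cell_mat[t, rot[[s[t]]]]
      safe_cor(colMeans(sh[oi, , drop = FALSE]),
               colMeans(sh[ei, , drop = FALSE]))
    }, numeric(1))
  })
  degenerate <- is.na(cc_true)
  threshold <- if (all(is.na(null_ccs))) NA_real_
               else quantile(null_ccs, 0.95, na.rm = TRUE, names = FALSE)
  list(cc_true = cc_true, null_ccs = null_ccs, threshold = threshold,
       reliable = !degenerate && !is.na(threshold) && cc_true > threshold,
       degenerate = degenerate)
}

# cache of separable Gaussian filter operators keyed by (size, sigma)
.ssim_cache <- new.env(parent = emptyenv())

# Left-multiplication matrix performing a 1-D Gaussian filter with
# scipy-style 'reflect' boundary handling; radius = floor(truncate*sigma + .5)
.gauss_op <- function(n, sigma = 1.5, truncate = 3.5) {
  key <- sprintf("%d_%g_%g", n, sigma, truncate)
  if (!is.null(.ssim_cache[[key]])) return(.ssim_cache[[key]])
  r <- as.integer(truncate * sigma + 0.5)
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  pad_idx <- c(rev(seq_len(r)), seq_len(n), rev(n - seq_len(r) + 1L))  # reflect
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- numeric(n)
    for (j in seq_len(2L * r + 1L)) {
      src <- pad_idx[i + j - 1L]
      row[src] <- row[src] + k[j]
    }
    M[i, ] <- row
  }
  .ssim_cache[[key]] <- list(M = M, radius = r)
  .ssim_cache[[key]]
}

#' Structural similarity index between two image patches
#'
#' Gaussian-weighted SSIM with the standard constants K1 = 0.01, K2 = 0.03
#' and window sigma = 1.5 (11 x 11 support), without sample-covariance
#' correction; the dynamic range is taken from the pooled patch pair. The
#' local SSIM map is averaged after cropping the filter radius, matching
#' reference implementations.
#'
#' @param patch_a,patch_b equal-shaped numeric matrices.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param K1,K2 stabilization constants.
#' @param data_range dynamic range; defaults to the pooled range of both
#'   patches.
#' @return scalar SSIM in `[-1, 1]`.
#' @export
compute_ssi <- function(patch_a, patch_b, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                        data_range = NULL) {
  if (!all(dim(patch_a) == dim(patch_b))) stop("patch shapes differ")
  if (is.null(data_range))
    data_range <- max(patch_a, patch_b) - min(patch_a, patch_b)
  if (data_range == 0) return(1)

  opr <- .gauss_op(nrow(patch_a), sigma)
  opc <- .gauss_op(ncol(patch_a), sigma)
  f <- function(m) opr$M %*% m %*% t(opc$M)

  ux <- f(patch_a); uy <- f(patch_b)
  vx <- f(patch_a * patch_a) - ux * ux
  vy <- f(patch_b * patch_b) - uy * uy
  vxy <- f(patch_a * patch_b) - ux * uy

  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))

  r <- opr$radius
  rows <- (r + 1L):(nrow(S) - r); cols <- (r + 1L):(ncol(S) - r)
  mean(S[rows, cols, drop = FALSE])
}

#' ROI morphological-stability test
#'
#' Compares the similarity between a cell's day-1 and day-k ROI windows with
#' a null distribution of similarities between the day-1 window and random
#' windows from the comparison day's field. Stable when the true value
#' exceeds the null's 95th percentile. The similarity metric is SSIM by
#' default; the 2-D correlation coefficient gives similar decisions and is
#' available via `metric`.
#'
#' @param patch_day1,patch_dayk equal-shaped ROI windows.
#' @param null_windows list of at least 50 random windows from the
#'   comparison day (see [sample_null_windows()]).
#' @param metric `"ssim"` or `"corr2d"`.
#' @return list: `ssi_true`, `null_ssis`, `threshold`, `stable`, `metric`.
#' @export
roi_stability_test <- function(patch_day1, patch_dayk, null_windows,
                               metric = c("ssim", "corr2d")) {
  metric <- match.arg(metric)
  if (length(null_windows) < 50L) stop("need at least 50 null windows")
  simf <- if (metric == "ssim") compute_ssi
          else function(a, b) safe_cor(as.numeric(a), as.numeric(b))
  ssi_true <- simf(patch_day1, patch_dayk)
  null_ssis <- vapply(null_windows, function(w) simf(patch_day1, w), numeric(1))
  threshold <- quantile(null_ssis, 0.95, na.rm = TRUE, names = FALSE)
  list(ssi_true = ssi_true, null_ssis = null_ssis, threshold = threshold,
       stable = !is.na(ssi_true) && ssi_true > threshold, metric = metric)
}

#' Combine inclusion gates into per-day-pair cell sets
#'
#' For a (day 1, day k) comparison a cell is included iff it is reliable on
#' day 1 and on day k, its ROI is stable for that pair, and both sessions
#' pass behavioral inclusion. Also returns the strict set of cells passing
#' every gate on all days.
#'
#' @param reliable cells x days logical matrix.
#' @param stable cells x days logical matrix; column k holds the (1, k) ROI
#'   decision (column 1 is ignored and treated as TRUE).
#' @param session_included logical vector per day.
#' @return list: `pairs` (named list, one integer cell-id vector per
#'   comparison day 2..n) and `strict` (cells passing all gates on all
#'   days).
#' @export
select_cells <- function(reliable, stable, session_included) {
  nd <- ncol(reliable)
  stopifnot(ncol(stable) == nd, length(session_included) == nd)
  pairs <- list()
  for (k in 2:nd) {
    ok <- reliable[, 1L] & reliable[, k] & stable[, k] &
      (session_included[1L] & session_included[k])
    pairs[[as.character(k)]] <- which(ok)
  }
  strict_ok <- rowSums(reliable) == nd &
    rowSums(stable[, -1L, drop = FALSE]) == (nd - 1L) &
    all(session_included)
  list(pairs = pairs, strict = which(strict_ok))
}
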