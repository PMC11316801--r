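#' Trial-balanced resampling index sets
#'
#' Draws, in each iteration and without replacement, the global minimum
#' group size from every group, removing the correct/incorrect (or
#' per-type) imbalance of trained animals.
#'
#' @param labels per-trial group labels (factor or character).
#' @param n_iter number of iterations.
#' @param seed integer seed.
#' @return list of `n_iter` integer index vectors (concatenated per-group
#'   draws, group order preserved).
#' @export
balance_trials <- function(labels, n_iter = 100L, seed = NULL) {
  if (!is.factor(labels)) labels <- factor(labels)
  groups <- split(seq_along(labels), labels)  # empty levels are kept
  sizes <- lengths(groups)
  if (any(sizes == 0L))
    stop(sprintf("group '%s' has no trials", names(groups)[which(sizes == 0L)[1]]))
  m <- min(sizes)
  with_seed(seed, {
    lapply(seq_len(n_iter), function(it)
      unlist(lapply(groups, function(g) sample(g, m)), use.names = FALSE))
  })
}

# Fast two-sided Wilcoxon signed-rank p-value for paired differences.
# Exact (psignrank) without ties/zeros, tie-corrected normal approximation
# otherwise.
signed_rank_p <- function(d) {
  d <- d[d != 0 & is.finite(d)]
  n <- length(d)
  if (n < 2L) return(NA_real_)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (!anyDuplicated(r)) {
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    min(p, 1)
  } else {
    tie <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    if (sig2 <= 0) return(NA_real_)
    2 * stats::pnorm(-abs((V - n * (n + 1) / 4) / sqrt(sig2)))
  }
}

#' Task-variable preference of one cell
#'
#' Resamples trials with replacement (balanced to the smaller class) over
#' `n_iter` iterations and tests, per time bin, whether activity differs
#' between the two classes with a paired Wilcoxon signed-rank test. By
#' default each iteration yields one signed-rank p (pairing resampled
#' trials within the iteration) and the per-bin p is the median across
#' iterations; `mode = "across_iterations"` instead pairs the iteration
#' means by resample index (anticonservative; kept for sensitivity checks).
#' A cell has a significant preference when p < `alpha` for at least
#' `min_run` consecutive bins; the preferred class is the one with higher
#' mean activity within the qualifying run.
#'
#' @param cell_mat trials x bins matrix for one cell.
#' @param classes per-trial class labels (two levels).
#' @param n_iter resampling iterations.
#' @param alpha per-bin significance level.
#' @param min_run minimum significant run length in bins (5 bins = 0.5 s).
#' @param seed integer seed.
#' @param mode p-value aggregation, see above.
#' @return list: `significant`, `preferred_class`, `run_start_bin`,
#'   `run_length`, `p_by_bin`.
#' @export
preference_test <- function(cell_mat, classes, n_iter = 100L, alpha = 0.05,
                            min_run = 5L, seed = NULL,
                            mode = c("per_iteration", "across_iterations")) {
  mode <- match.arg(mode)
  lev <- unique(classes)
  if (length(lev) != 2L) stop("classes must have exactly two levels")
  ia <- which(classes == lev[1]); ib <- which(classes == lev[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both classes need at least 2 trials")
  m <- min(length(ia), length(ib))
  nb <- ncol(cell_mat)

  with_seed(seed, {
    if (mode == "per_iteration") {
      pmat <- matrix(NA_real_, n_iter, nb)
      mean_a <- mean_b <- matrix(0, n_iter, nb)
      for (it in seq_len(n_iter)) {
        sa <- cell_mat[sample(ia, m, replace = TRUE), , drop = FALSE]
        sb <- cell_mat[sample(ib, m, replace = TRUE), , drop = FALSE]
        pmat[it, ] <- .signed_rank_p_cols(sa - sb)
        mean_a[it, ] <- colMeans(sa); mean_b[it, ] <- colMeans(sb)
      }
      p_by_bin <- apply(pmat, 2L, median, na.rm = TRUE)
      ma <- colMeans(mean_a); mb <- colMeans(mean_b)
    } else {
      mean_a <- mean_b <- matrix(0, n_iter, nb)
      for (it in seq_len(n_iter)) {
        mean_a[it, ] <- colMeans(cell_mat[sample(ia, m, replace = TRUE), , drop = FALSE])
        mean_b[it, ] <- colMeans(cell_mat[sample(ib, m, replace = TRUE), , drop = FALSE])
      }
      p_by_bin <- .signed_rank_p_cols(mean_a - mean_b)
      ma <- colMeans(mean_a); mb <- colMeans(mean_b)
    }
    p_by_bin[is.na(p_by_bin)] <- 1
    run <- find_run(p_by_bin < alpha, min_run)
    if (is.null(run)) {
      list(significant = FALSE, preferred_class = NA, run_start_bin = NA_integer_,
           run_length = 0L, p_by_bin = p_by_bin)
    } else {
      bins <- run[["start"]]:(run[["start"]] + run[["length"]] - 1L)
      pref <- if (mean(ma[bins]) >= mean(mb[bins])) lev[1] else lev[2]
      list(significant = TRUE, preferred_class = pref,
           run_start_bin = run[["start"]], run_length = run[["length"]],
           p_by_bin = p_by_bin)
    }
  })
}

#' Cross-day single-cell response correlation
#'
#' Pearson correlation, per cell, between the mean response over odd trials
#' on day 1 and the mean response over even trials on day k, concatenated
#' across the grouping's classes (trial types or preferred-variable
#' classes).
#'
#' @param tensor_day1,tensor_dayk `trial_tensor`s with identical cell sets.
#' @param classes_day1,classes_dayk per-trial grouping labels; defaults to
#'   the tensors' trial-type labels.
#' @return numeric vector, one CC per cell; `NA` (with attribute
#'   `n_undefined`) where a zero-variance mean made the correlation
#'   undefined.
#' @export
crossday_response_cc <- function(tensor_day1, tensor_dayk,
                                 classes_day1 = attr(tensor_day1, "labels"),
                                 classes_dayk = attr(tensor_dayk, "labels")) {
  nc <- dim(tensor_day1)[1]
  stopifnot(dim(tensor_dayk)[1] == nc)
  lev <- sort(unique(c(classes_day1, classes_dayk)))
  out <- vapply(seq_len(nc), function(i) {
    v1 <- unlist(lapply(lev, function(cl) {
      tr <- which(classes_day1 == cl)
      if (!length(tr)) return(NULL)
      colMeans(matrix(tensor_day1[i, tr[odd_idx(length(tr))], ],
                      ncol = dim(tensor_day1)[3]))
    }))
    vk <- unlist(lapply(lev, function(cl) {
      tr <- which(classes_dayk == cl)
      if (!length(tr)) return(NULL)
      colMeans(matrix(tensor_dayk[i, tr[even_idx(length(tr))], ],
                      ncol = dim(tensor_dayk)[3]))
    }))
    if (length(v1) != length(vk)) return(NA_real_)
    safe_cor(v1, vk)
  }, numeric(1))
  structure(out, n_undefined = sum(is.na(out)))
}

#' Cross-validated population-vector correlation matrix
#'
#' Per iteration, resamples the population to `n_cells` cells and balances
#' trials of the requested types to the minimum per-type count, then
#' correlates the population vectors (activity across cells) at every pair
#' of time bins. Within-day matrices are built from two disjoint trial
#' halves; cross-day matrices compare all resampled day-1 trials with all
#' resampled day-k trials. Matrices are averaged over iterations; the
#' per-iteration diagonal is kept for correct-versus-incorrect comparisons.
#'
#' @param tensor_day1,tensor_dayk `trial_tensor`s (pass the same object for
#'   the within-day case).
#' @param condition_types trial types defining the condition (e.g.
#'   `c("CL", "CR")` for correct trials).
#' @param n_cells fixed cell count resampled in each iteration.
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param within_day logical; disjoint-halves mode.
#' @return list: `mean_matrix` (bins x bins), `iter_diag` (n_iter x bins),
#'   `n_cells`, `within_day`.
#' @export
population_vector_correlation <- function(tensor_day1, tensor_dayk = tensor_day1,
                                          condition_types = c("CL", "CR"),
                                          n_cells,
                                          n_iter = 100L, seed = NULL,
                                          within_day = missing(tensor_dayk)) {
  nc <- dim(tensor_day1)[1]
  if (n_cells > nc) stop("fewer cells available than n_cells")
  lab1 <- attr(tensor_day1, "labels"); labk <- attr(tensor_dayk, "labels")
  nb <- dim(tensor_day1)[3]
  t1 <- lapply(condition_types, function(cl) which(lab1 == cl))
  tk <- lapply(condition_types, function(cl) which(labk == cl))
  if (any(lengths(t1) == 0L) || any(lengths(tk) == 0L))
    stop("a condition trial type has no trials")

  with_seed(seed, {
    acc <- matrix(0, nb, nb)
    iter_diag <- matrix(NA_real_, n_iter, nb)
    for (it in seq_len(n_iter)) {
      cells <- sample.int(nc, n_cells)
      if (within_day) {
        m <- min(lengths(t1))
        m2 <- m %/% 2L
        if (m2 < 1L) stop("too few trials for disjoint halves")
        h1 <- h2 <- integer(0)
        for (g in t1) {
          s <- sample(g, 2L * m2)
          h1 <- c(h1, s[seq_len(m2)]); h2 <- c(h2, s[m2 + seq_len(m2)])
        }
        M1 <- apply(tensor_day1[cells, h1, , drop = FALSE], c(1, 3), mean)
        M2 <- apply(tensor_day1[cells, h2, , drop = FALSE], c(1, 3), mean)
      } else {
        m1 <- min(lengths(t1)); mk <- min(lengths(tk))
        s1 <- unlist(lapply(t1, function(g) sample(g, m1)))
        sk <- unlist(lapply(tk, function(g) sample(g, mk)))
        M1 <- apply(tensor_day1[cells, s1, , drop = FALSE], c(1, 3), mean)
        M2 <- apply(tensor_dayk[cells, sk, , drop = FALSE], c(1, 3), mean)
      }
      cc <- suppressWarnings(cor(M1, M2))   # bins x bins over the cell dim
      cc[is.na(cc)] <- 0
      acc <- acc + cc
      iter_diag[it, ] <- diag(cc)
    }
    list(mean_matrix = acc / n_iter, iter_diag = iter_diag,
         n_cells = n_cells, within_day = within_day)
  })
}

#' Compare correct and incorrect PV-correlation diagonals
#'
#' Flags the bins at which the mean correct-trial diagonal correlation
#' exceeds the 95th percentile of the incorrect-trial iteration values.
#'
#' @param pv_correct,pv_incorrect results of
#'   [population_vector_correlation()] for the two conditions.
#' @return logical vector per bin.
#' @export
pv_diagonal_comparison <- function(pv_correct, pv_incorrect) {
  thr <- apply(pv_incorrect$iter_diag, 2L, quantile, probs = 0.95, na.rm = TRUE)
  diag(pv_correct$mean_matrix) > thr
}

#' Latency ordering of cells
#'
#' Orders cells by the arg-max bin of their mean response over odd trials
#' (ties broken by cell id); the ordering is meant to be applied to
#' even-trial means for display.
#'
#' @param tensor a `trial_tensor`.
#' @return list: `order` (cell permutation), `peak_bin` per cell, and
#'   `display` (even-trial mean matrix, cells x bins, unsorted).
#' @export
latency_sort <- function(tensor) {
  nt <- dim(tensor)[2]
  oi <- odd_idx(nt); ei <- even_idx(nt)
  odd_mean <- apply(tensor[, oi, , drop = FALSE], c(1, 3), mean)
  even_mean <- if (length(ei))
    apply(tensor[, ei, , drop = FALSE], c(1, 3), mean) else odd_mean
  peak <- apply(odd_mean, 1L, which.max)
  list(order = order(peak, seq_along(peak)), peak_bin = peak,
       display = even_mean)
}
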