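#' Binary class labels for a task variable
#'
#' Deterministic trial-type partitions: context groups CL+IR (context 1)
#' against IL+CR (context 2); motor groups CL+IL (left) against IR+CR
#' (right); both outcome variables group CL+CR (correct) against IR+IL
#' (incorrect). Class 1 is context 1 / left / correct.
#'
#' @param trial_type vector of trial types (`CL`, `IR`, `IL`, `CR`).
#' @param variable one of `context`, `motor`, `post_decision_outcome`,
#'   `post_trial_outcome`.
#' @return integer classes (1/2); errors on aborted trials.
#' @export
variable_labels <- function(trial_type, variable) {
  variable_class_of(trial_type, match.arg(variable, .VARIABLES))
}

#' Homogenize trials and split into disjoint train/test sets
#'
#' Each trial type's trials are first partitioned into two disjoint halves;
#' each half is then resampled with replacement to a common per-type target
#' count. Train and test therefore never share an underlying trial, and
#' both sets hold equal numbers of every trial type.
#'
#' @param trial_types per-trial type labels (aborted trials must already be
#'   excluded).
#' @param target per-type sample count; defaults to the minimum per-type
#'   count of the session.
#' @param seed integer seed.
#' @return list: `train`, `test` (indices into `trial_types`, possibly
#'   repeated), `train_half`, `test_half` (the underlying disjoint halves),
#'   `target`.
#' @export
homogenize_and_split <- function(trial_types, target = NULL, seed = NULL) {
  groups <- split(seq_along(trial_types), trial_types)
  if (any(!names(groups) %in% .TRIAL_TYPES))
    stop("trial_types must contain only CL/IR/IL/CR")
  if (length(groups) < 4L || any(lengths(groups) < 2L))
    stop("every trial type needs at least 2 trials")
  if (is.null(target)) target <- min(lengths(groups))
  with_seed(seed, {
    train <- test <- integer(0)
    train_half <- test_half <- integer(0)
    for (g in groups) {
      g <- sample(g)                       # random partition
      n1 <- length(g) %/% 2L
      if (length(g) %% 2L == 1L && runif(1) < 0.5) n1 <- n1 + 1L
      h1 <- g[seq_len(n1)]; h2 <- g[-seq_len(n1)]
      train_half <- c(train_half, h1); test_half <- c(test_half, h2)
      train <- c(train, sample(h1, target, replace = TRUE))
      test <- c(test, sample(h2, target, replace = TRUE))
    }
    list(train = train, test = test, train_half = train_half,
         test_half = test_half, target = target)
  })
}

# fit + predict wrappers around the compiled dual-coordinate-descent SVM
svm_fit <- function(X, classes, C = 1, max_epochs = 200L, tol = 1e-3) {
  y <- ifelse(classes == 1L, 1, -1)
  .svm_dcd_fit(as.matrix(X), y, C, max_epochs, tol)
}

svm_predict <- function(fit, X) {
  s <- as.numeric(as.matrix(X) %*% fit$w + fit$b)
  ifelse(s >= 0, 1L, 2L)
}

# shared per-bin decode loop. Returns n_iter x n_bins performance matrix.
.decode_iterations <- function(train_tensor, test_tensor, variable, bins,
                               n_iter, C, seed, same_day) {
  lab_train <- attr(train_tensor, "labels")
  lab_test <- if (same_day) lab_train else attr(test_tensor, "labels")
  perf <- matrix(NA_real_, n_iter, length(bins))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      hs <- homogenize_and_split(lab_train)
      tr_idx <- hs$train
      if (same_day) {
        te_idx <- hs$test
        te_tensor <- train_tensor
        y_test <- variable_class_of(lab_train[te_idx], variable)
      } else {
        hs2 <- homogenize_and_split(lab_test)
        te_idx <- hs2$test
        te_tensor <- test_tensor
        y_test <- variable_class_of(lab_test[te_idx], variable)
      }
      y_train <- variable_class_of(lab_train[tr_idx], variable)
      if (length(unique(y_train)) < 2L) next   # degenerate, skip iteration
      for (bi in seq_along(bins)) {
        b <- bins[bi]
        Xtr <- t(matrix(train_tensor[, tr_idx, b], ncol = length(tr_idx)))
        Xte <- t(matrix(te_tensor[, te_idx, b], ncol = length(te_idx)))
        fit <- svm_fit(Xtr, y_train, C)
        perf[it, bi] <- mean(svm_predict(fit, Xte) == y_test)
      }
    }
  })
  perf
}

# assemble a decoding_curve from an iteration x bin performance matrix
.make_curve <- function(perf, bins, bin_s, variable, train_day, test_day,
                        unit, n_iter) {
  structure(list(
    mean_performance = colMeans(perf, na.rm = TRUE),
    ci_low = apply(perf, 2L, quantile, probs = 0.05, na.rm = TRUE, names = FALSE),
    ci_high = apply(perf, 2L, quantile, probs = 0.95, na.rm = TRUE, names = FALSE),
    iter_performance = perf,
    bins = bins, bin_time_s = (bins - 1L) * bin_s,
    variable = variable, train_day = train_day, test_day = test_day,
    unit = unit, n_iter = n_iter
  ), class = "decoding_curve")
}

#' Per-timebin SVM decoding within or across days
#'
#' In each of `n_iter` iterations, trials are homogenized (equal per-type
#' counts resampled with replacement from disjoint halves) and a binary
#' linear SVM (C = 1) is trained per time bin on the reference day's train
#' set. Same-day curves are scored on the held-out half; cross-day curves
#' on homogenized trials of the test day. The curve reports the mean and
#' the bootstrap 5th/95th percentile CIs per bin.
#'
#' @param train_tensor reference-day `trial_tensor` restricted to the
#'   included cells (single-cell decoding: a one-cell tensor).
#' @param test_tensor test-day tensor with the same cells, or `NULL` for
#'   the within-day case.
#' @param variable task variable name.
#' @param bins bin indices to decode (default: all bins).
#' @param n_iter bootstrap iterations.
#' @param C SVM cost parameter.
#' @param seed integer seed.
#' @param unit label carried in the result.
#' @param train_day,test_day day indices carried in the result.
#' @return a `decoding_curve`: `mean_performance`, `ci_low`, `ci_high` per
#'   bin, the per-iteration matrix, and metadata.
#' @export
decode_across_days <- function(train_tensor, test_tensor = NULL, variable,
                               bins = NULL, n_iter = 100L, C = 1,
                               seed = NULL, unit = "experiment_population",
                               train_day = 1L, test_day = NULL) {
  variable <- match.arg(variable, .VARIABLES)
  same_day <- is.null(test_tensor)
  if (same_day) test_day <- train_day
  if (is.null(test_day)) test_day <- NA_integer_
  if (!same_day && dim(train_tensor)[1] != dim(test_tensor)[1])
    stop("train and test tensors must hold the same cells")
  if (is.null(bins)) bins <- seq_len(dim(train_tensor)[3])
  perf <- .decode_iterations(train_tensor, test_tensor, variable, bins,
                             n_iter, C, seed, same_day)
  .make_curve(perf, bins, attr(train_tensor, "bin_duration_s") %||% 0.1,
              variable, train_day, test_day, unit, n_iter)
}

#' Significant-encoding call from a decoding curve
#'
#' A curve encodes its variable when the lower 5th-percentile CI exceeds
#' chance (0.5) for at least `min_run` consecutive bins. For the outcome
#' partition the qualifying run's position assigns the variable: runs in
#' bins up to `trial_end_bin` are post-decision outcome, runs after it are
#' post-trial outcome (a cell can receive both).
#'
#' @param curve a `decoding_curve`.
#' @param trial_end_bin 1-based bin of trial end (61 at 10 Hz defaults).
#' @param min_run minimum run length (5 bins = 0.5 s).
#' @return list: `significant`, `qualifying_run` (start bin, length) or
#'   `NULL`, and `assigned_variables`.
#' @export
significant_encoding <- function(curve, trial_end_bin = 61L, min_run = 5L) {
  above <- curve$ci_low > 0.5
  run <- find_run(above, min_run)
  outcome <- curve$variable %in% c("post_decision_outcome", "post_trial_outcome")
  if (!outcome) {
    assigned <- if (!is.null(run)) curve$variable else character(0)
    return(list(significant = !is.null(run),
                qualifying_run = run, assigned_variables = assigned))
  }
  # outcome: search the two regions separately
  pre <- curve$bins <= trial_end_bin
  run_pre <- find_run(above & pre, min_run)
  run_post <- find_run(above & !pre, min_run)
  assigned <- c(if (!is.null(run_pre)) "post_decision_outcome",
                if (!is.null(run_post)) "post_trial_outcome")
  list(significant = length(assigned) > 0L,
       qualifying_run = run_pre %||% run_post,
       assigned_variables = assigned %||% character(0))
}

#' Pseudo-population decoding across experiments
#'
#' Pools cells across experiments and builds pseudo-trials: per pseudo-trial
#' and class, every cell independently contributes one of its own trials of
#' that class (types within the class sampled evenly). Train and test
#' pseudo-trials draw from disjoint halves of each experiment's real
#' trials. Decoding then proceeds as in [decode_across_days()].
#'
#' @param train_tensors,test_tensors per-experiment lists of
#'   `trial_tensor`s (same cell sets across the two lists); pass
#'   `test_tensors = NULL` for within-day decoding.
#' @param variable task variable name.
#' @param n_pseudo pseudo-trials per class in each of train/test.
#' @param bins bin indices to decode (default: all).
#' @param n_iter bootstrap iterations.
#' @param C SVM cost parameter.
#' @param seed integer seed.
#' @param train_day,test_day metadata labels.
#' @return a `decoding_curve` with `unit = "pseudopopulation"`.
#' @export
pseudopopulation_decode <- function(train_tensors, test_tensors = NULL,
                                    variable, n_pseudo = 40L, bins = NULL,
                                    n_iter = 100L, C = 1, seed = NULL,
                                    train_day = 1L, test_day = NULL) {
  variable <- match.arg(variable, .VARIABLES)
  if (length(train_tensors) < 2L) stop("need at least 2 experiments")
  same_day <- is.null(test_tensors)
  if (same_day) test_day <- train_day
  if (is.null(bins)) bins <- seq_len(dim(train_tensors[[1]])[3])
  nb <- length(bins)
  ncell <- vapply(train_tensors, function(t) dim(t)[1], integer(1))
  n_total <- sum(ncell)

  # per experiment: trial indices by (type), train day and test day
  types_by <- function(tensors) lapply(tensors, function(t)
    split(seq_along(attr(t, "labels")), attr(t, "labels")))
  g_train <- types_by(train_tensors)
  g_test <- if (same_day) g_train else types_by(test_tensors)

  class_types <- list(`1` = NULL, `2` = NULL)
  for (ty in .TRIAL_TYPES)
    class_types[[variable_class_of(ty, variable)]] <-
      c(class_types[[variable_class_of(ty, variable)]], ty)

  build_X <- function(tensors, halves, b_all) {
    # matrix (2*n_pseudo) x n_total for each bin: list over bins
    Xs <- lapply(seq_len(nb), function(i) matrix(NA_real_, 2L * n_pseudo, n_total))
    y <- rep(c(1L, 2L), each = n_pseudo)
    col0 <- 0L
    for (e in seq_along(tensors)) {
      tens <- tensors[[e]]
      for (ci in 1:2) {
        pool_by_type <- halves[[e]][class_types[[ci]]]
        pool_by_type <- pool_by_type[lengths(pool_by_type) > 0L]
        if (!length(pool_by_type)) stop("empty class for an experiment")
        for (j in seq_len(n_pseudo)) {
          row <- (ci - 1L) * n_pseudo + j
          for (cell in seq_len(ncell[e])) {
            ty <- sample(length(pool_by_type), 1L)
            tr <- pool_by_type[[ty]][sample.int(length(pool_by_type[[ty]]), 1L)]
            for (i in seq_len(nb))
              Xs[[i]][row, col0 + cell] <- tens[cell, tr, b_all[i]]
          }
        }
      }
      col0 <- col0 + ncell[e]
    }
    list(X = Xs, y = y)
  }

  perf <- matrix(NA_real_, n_iter, nb)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      # disjoint halves of every experiment's per-type trials
      halve <- function(groups) lapply(groups, function(g) {
        g <- sample(g); n1 <- max(1L, length(g) %/% 2L)
        list(h1 = g[seq_len(n1)], h2 = g[-seq_len(n1)])
      })
      h_train <- lapply(g_train, halve)
      h_test <- if (same_day) h_train else lapply(g_test, halve)
      take <- function(h, which_half) lapply(h, function(per_exp)
        lapply(per_exp, function(x) if (which_half == 1L) x$h1 else x$h2))
      tr <- build_X(train_tensors, take(h_train, 1L), bins)
      te <- build_X(if (same_day) train_tensors else test_tensors,
                    take(h_test, 2L), bins)
      for (i in seq_len(nb)) {
        fit <- svm_fit(tr$X[[i]], tr$y, C)
        perf[it, i] <- mean(svm_predict(fit, te$X[[i]]) == te$y)
      }
    }
  })
  .make_curve(perf, bins,
              attr(train_tensors[[1]], "bin_duration_s") %||% 0.1,
              variable, train_day, test_day, "pseudopopulation", n_iter)
}

#' Cell-subset controls for decoding comparisons
#'
#' `equal_n` draws a random subset of fixed size. `match_performance`
#' searches (doubling then bisection over subset size) for the smallest
#' random subset whose day-1 mean window performance reaches `target`.
#'
#' @param train_tensor day-1 `trial_tensor`.
#' @param variable task variable name.
#' @param mode `"equal_n"` or `"match_performance"`.
#' @param n subset size for `equal_n`.
#' @param target performance target for `match_performance`.
#' @param n_iter decoding iterations per evaluation.
#' @param seed integer seed.
#' @return list: `cells`, `performance` (achieved day-1 window mean),
#'   `success` (FALSE when the target is unreachable with all cells).
#' @export
subsample_controls <- function(train_tensor, variable,
                               mode = c("equal_n", "match_performance"),
                               n = NULL, target = 0.9, n_iter = 25L,
                               seed = NULL) {
  mode <- match.arg(mode)
  variable <- match.arg(variable, .VARIABLES)
  nc <- dim(train_tensor)[1]
  win <- .VARIABLE_WINDOWS[[variable]]
  bin_s <- attr(train_tensor, "bin_duration_s") %||% 0.1
  bins <- which((seq_len(dim(train_tensor)[3]) - 1L) * bin_s >= win[1] &
                (seq_len(dim(train_tensor)[3]) - 1L) * bin_s < win[2])

  eval_subset <- function(cells, s) {
    sub <- train_tensor[cells, , , drop = FALSE]
    attributes(sub)[c("labels", "bin_duration_s", "window")] <-
      attributes(train_tensor)[c("labels", "bin_duration_s", "window")]
    cv <- decode_across_days(sub, NULL, variable, bins = bins,
                             n_iter = n_iter, seed = s)
    mean(cv$mean_performance)
  }

  with_seed(seed, {
    if (mode == "equal_n") {
      if (is.null(n)) stop("equal_n requires n")
      if (n > nc) stop("n exceeds available cells")
      cells <- if (n == nc) seq_len(nc) else sort(sample.int(nc, n))
      return(list(cells = cells,
                  performance = eval_subset(cells, sample.int(1e6, 1)),
                  success = TRUE, mode = mode))
    }
    # match_performance: doubling then bisection on subset size
    full_perf <- eval_subset(seq_len(nc), sample.int(1e6, 1))
    if (full_perf < target)
      return(list(cells = integer(0), performance = full_perf,
                  success = FALSE, mode = mode))
    size <- 1L
    repeat {
      cells <- sort(sample.int(nc, min(size, nc)))
      if (eval_subset(cells, sample.int(1e6, 1)) >= target || size >= nc) break
      size <- min(2L * size, nc)
    }
    lo <- max(1L, size %/% 2L); hi <- size
    best <- cells
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      cells <- sort(sample.int(nc, mid))
      if (eval_subset(cells, sample.int(1e6, 1)) >= target) {
        hi <- mid; best <- cells
      } else lo <- mid
    }
    # verify the returned subset; grow it if the re-evaluation falls short
    perf <- eval_subset(best, sample.int(1e6, 1))
    while (perf < target && length(best) < nc) {
      extra <- sample(setdiff(seq_len(nc), best),
                      min(max(1L, length(best) %/% 4L), nc - length(best)))
      best <- sort(c(best, extra))
      perf <- eval_subset(best, sample.int(1e6, 1))
    }
    list(cells = best, performance = perf, success = TRUE, mode = mode)
  })
}
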