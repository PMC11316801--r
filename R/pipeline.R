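.default_pipeline_config <- function() {
  list(
    n_experiments = 3L,
    n_mice = 3L,
    task = list(),                      # overrides for task_config()
    tau_by_variable = c(context = 7.3, motor = 1.9,
                        post_decision_outcome = 2.2,
                        post_trial_outcome = 35.7),
    qc = list(n_reliability_iter = 100L, n_null_windows = 100L),
    responses = list(n_iter = 100L, run_preference = TRUE),
    decoding = list(n_iter = 100L, C = 1, bins = "windows"),
    seed = 1L,
    out_dir = NULL
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, builds the embedded
#' [task_config()], and verifies that every task-variable integration
#' window is exactly 1.5 s wide.
#'
#' @param config named list of overrides (possibly nested); `NULL` or an
#'   empty list yields the full defaults.
#' @return a normalized `pipeline_config` list with the resolved
#'   `task_config` under `$task_config`.
#' @export
validate_config <- function(config = list()) {
  defaults <- .default_pipeline_config()
  config <- config %||% list()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop_config("unknown configuration keys: %s", paste(bad, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        nm != "task") {
      bad2 <- setdiff(names(config[[nm]]), names(defaults[[nm]]))
      if (length(bad2))
        stop_config("unknown configuration keys under %s: %s", nm,
                    paste(bad2, collapse = ", "))
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else defaults[[nm]] <- config[[nm]]
  }
  cfg <- defaults
  cfg$task_config <- do.call(task_config, cfg$task)
  if (!cfg$decoding$bins %in% c("windows", "all"))
    stop_config("decoding$bins must be 'windows' or 'all'")
  widths <- vapply(.VARIABLE_WINDOWS, diff, numeric(1))
  if (any(abs(widths - 1.5) > 1e-9))
    stop_config("task-variable windows must be exactly 1.5 s wide")
  if (cfg$n_experiments < 1L) stop_config("n_experiments must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

# window bins (1-based) of a variable at the tensor's bin duration
window_bins <- function(variable, n_bins, bin_s = 0.1) {
  win <- .VARIABLE_WINDOWS[[variable]]
  tt <- (seq_len(n_bins) - 1L) * bin_s
  which(tt >= win[1] - 1e-9 & tt <= win[2] + 1e-9)
}

#' Run the full analysis pipeline on synthetic experiments
#'
#' Stages, in order: simulate experiment bundles; preprocess (neuropil
#' correction, dF/F, trial alignment); QC gates (session inclusion,
#' reliability, ROI stability, cell selection); single-cell responses
#' (preference fractions, cross-day correlation decay fits); per-timebin
#' SVM decoding of the four task variables trained on day 1; stability
#' quantification (window integration, day-1 normalization, exponential
#' decay fits with SSE/R2 filtering) and, when enough experiments are
#' available, LME comparisons of rankit-transformed time constants. Fully
#' deterministic given the config's master seed.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a raw
#'   list of overrides).
#' @return a `report_bundle` list of result tables (see the fields of the
#'   return value) carrying the master seed and a config hash.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  tc <- config$task_config
  seed <- config$seed

  # ---- simulate ----
  bundles <- lapply(seq_len(config$n_experiments), function(e)
    generate_experiment(tc, config$tau_by_variable,
                        seed = derive_seed(seed, paste0("exp", e)),
                        mouse_id = paste0("m", ((e - 1L) %% config$n_mice) + 1L),
                        experiment_id = paste0("e", e)))

  # ---- preprocess ----
  prep <- lapply(bundles, preprocess_bundle)

  # ---- qc ----
  session_tab <- NULL
  qc_tab <- NULL
  selections <- vector("list", length(bundles))
  for (e in seq_along(bundles)) {
    b <- bundles[[e]]; nd <- length(b$days); nc <- tc$n_cells
    inc <- logical(nd)
    for (d in seq_len(nd)) {
      si <- check_session_inclusion(b$days[[d]]$trials)
      inc[d] <- si$included
      session_tab <- rbind(session_tab, data.frame(
        experiment = b$meta$experiment_id, mouse = b$meta$mouse_id, day = d,
        n_CL = si$n_CL, n_IR = si$n_IR, n_IL = si$n_IL, n_CR = si$n_CR,
        min_count = si$min_count, performance = si$performance,
        included = si$included))
    }
    reliable <- matrix(FALSE, nc, nd)
    for (d in seq_len(nd)) {
      tens <- prep[[e]]$tensors[[d]]
      corr_tr <- which(attr(tens, "labels") %in% c("CL", "CR"))
      for (i in seq_len(nc)) {
        rt <- reliability_test(
          matrix(tens[i, corr_tr, ], ncol = dim(tens)[3]),
          n_iter = config$qc$n_reliability_iter,
          seed = derive_seed(seed, sprintf("rel_%d_%d_%d", e, d, i)))
        reliable[i, d] <- rt$reliable
      }
    }
    stable <- matrix(TRUE, nc, nd)
    for (d in 2:nd) {
      for (i in seq_len(nc)) {
        nw <- sample_null_windows(
          b$roi$fields[[d]], b$roi$patch_px, n = config$qc$n_null_windows,
          exclude_center = b$roi$centers[[d]][i, ],
          seed = derive_seed(seed, sprintf("null_%d_%d_%d", e, d, i)))
        st <- roi_stability_test(b$days[[1]]$roi_patches[i, , ],
                                 b$days[[d]]$roi_patches[i, , ], nw)
        stable[i, d] <- st$stable
        qc_tab <- rbind(qc_tab, data.frame(
          experiment = b$meta$experiment_id, cell_id = i, day = d,
          reliable_day1 = reliable[i, 1L], reliable = reliable[i, d],
          ssi_true = st$ssi_true, ssi_threshold = st$threshold,
          stable = st$stable))
      }
    }
    selections[[e]] <- select_cells(reliable, stable, inc)
    selections[[e]]$reliable <- reliable
  }

  # ---- responses: preference fractions + cross-day CC decay ----
  pref_tab <- NULL
  cc_fit_tab <- NULL
  groupings <- c(context = "context", motor = "motor",
                 outcome = "post_decision_outcome")
  for (e in seq_along(bundles)) {
    tens1 <- prep[[e]]$tensors[[1L]]
    rel1 <- which(selections[[e]]$reliable[, 1L])
    if (config$responses$run_preference && length(rel1)) {
      for (g in names(groupings)) {
        cls <- variable_class_of(attr(tens1, "labels"), groupings[[g]])
        n_sig <- 0L
        for (i in rel1) {
          pr <- preference_test(
            matrix(tens1[i, , ], ncol = dim(tens1)[3]), cls,
            n_iter = config$responses$n_iter,
            seed = derive_seed(seed, sprintf("pref_%d_%s_%d", e, g, i)))
          n_sig <- n_sig + pr$significant
        }
        pref_tab <- rbind(pref_tab, data.frame(
          experiment = bundles[[e]]$meta$experiment_id, grouping = g,
          n_cells = length(rel1), n_significant = n_sig,
          fraction = n_sig / length(rel1)))
      }
    }
    # cross-day CC (by trial type) and per-cell decay fits
    nd <- length(prep[[e]]$tensors)
    cc_by_day <- matrix(NA_real_, tc$n_cells, nd)
    for (d in seq_len(nd)) {
      cc_by_day[, d] <- crossday_response_cc(tens1, prep[[e]]$tensors[[d]])
    }
    for (i in rel1) {
      if (sum(is.finite(cc_by_day[i, ])) < 3L) next
      f <- fit_decay(cc_by_day[i, ], seq_len(nd), "cc_decay")
      cc_fit_tab <- rbind(cc_fit_tab, data.frame(
        experiment = bundles[[e]]$meta$experiment_id,
        mouse = bundles[[e]]$meta$mouse_id, cell_id = i,
        amplitude = f$amplitude, tau = f$tau, sse = f$sse, r2 = f$r2,
        retained = is.finite(f$sse) && f$sse <= 1.6 && f$r2 > 0))
    }
  }

  # ---- decoding + stability ----
  curve_tab <- NULL
  np_tab <- NULL
  fit_tab <- NULL
  encoding_tab <- NULL
  for (e in seq_along(bundles)) {
    nd <- length(prep[[e]]$tensors)
    tens1 <- prep[[e]]$tensors[[1L]]
    nb <- dim(tens1)[3]
    sessions_ok <- session_tab$included[session_tab$experiment ==
                                          bundles[[e]]$meta$experiment_id]
    if (!sessions_ok[1L]) next          # reference day unusable
    subset_tensor <- function(tens, cells) {
      sub <- tens[cells, , , drop = FALSE]
      attributes(sub)[c("labels", "bin_duration_s", "window")] <-
        attributes(tens)[c("labels", "bin_duration_s", "window")]
      sub
    }
    for (v in .VARIABLES) {
      bins <- if (config$decoding$bins == "all") seq_len(nb)
              else window_bins(v, nb, attr(tens1, "bin_duration_s"))
      areas <- rep(NA_real_, nd); np_vals <- rep(NA_real_, nd)
      # day-1 within-day curve on all day-1-reliable cells: encoding calls
      rel1 <- which(selections[[e]]$reliable[, 1L])
      if (length(rel1) >= 2L) {
        cv1 <- decode_across_days(subset_tensor(tens1, rel1), NULL, v,
                                  bins = bins,
                                  n_iter = config$decoding$n_iter,
                                  C = config$decoding$C,
                                  seed = derive_seed(seed, sprintf("dec_%d_%s_1", e, v)),
                                  train_day = 1L)
        curve_tab <- rbind(curve_tab, data.frame(
          experiment = bundles[[e]]$meta$experiment_id, variable = v,
          unit = cv1$unit, train_day = 1L, test_day = 1L,
          bin_time_s = cv1$bin_time_s, mean = cv1$mean_performance,
          ci_low = cv1$ci_low, ci_high = cv1$ci_high))
        areas[1L] <- integrate_window(cv1)
        np_vals[1L] <- 1
        enc <- significant_encoding(cv1)
        encoding_tab <- rbind(encoding_tab, data.frame(
          experiment = bundles[[e]]$meta$experiment_id, variable = v,
          significant = enc$significant,
          assigned = paste(enc$assigned_variables, collapse = ";")))
      }
      for (d in seq_len(nd)[-1L]) {
        if (!sessions_ok[d]) next
        cells <- selections[[e]]$pairs[[as.character(d)]]
        if (length(cells) < 2L) next
        sub1 <- subset_tensor(tens1, cells)
        subk <- subset_tensor(prep[[e]]$tensors[[d]], cells)
        cv <- decode_across_days(sub1, subk, v, bins = bins,
                                 n_iter = config$decoding$n_iter,
                                 C = config$decoding$C,
                                 seed = derive_seed(seed, sprintf("dec_%d_%s_%d", e, v, d)),
                                 train_day = 1L, test_day = d)
        # train-day reference on the same matched cell set, so NP isolates
        # drift from day-to-day changes in the included population
        ref <- decode_across_days(sub1, NULL, v, bins = bins,
                                  n_iter = config$decoding$n_iter,
                                  C = config$decoding$C,
                                  seed = derive_seed(seed, sprintf("ref_%d_%s_%d", e, v, d)),
                                  train_day = 1L)
        curve_tab <- rbind(curve_tab, data.frame(
          experiment = bundles[[e]]$meta$experiment_id, variable = v,
          unit = cv$unit, train_day = 1L, test_day = d,
          bin_time_s = cv$bin_time_s, mean = cv$mean_performance,
          ci_low = cv$ci_low, ci_high = cv$ci_high))
        areas[d] <- integrate_window(cv)
        a_ref <- integrate_window(ref)
        np_vals[d] <- if (is.finite(a_ref) && a_ref > 0) areas[d] / a_ref
                      else NA_real_
      }
      np <- list(np = np_vals, days = seq_len(nd),
                 excluded = !is.finite(areas[1L]) || areas[1L] <= 0)
      np_tab <- rbind(np_tab, data.frame(
        experiment = bundles[[e]]$meta$experiment_id,
        mouse = bundles[[e]]$meta$mouse_id, variable = v,
        day = seq_len(nd), area = areas, np = np$np,
        excluded = np$excluded))
      if (!np$excluded && sum(is.finite(np$np)) >= 3L) {
        f <- fit_decay(np$np, seq_len(nd), "normalized")
        fit_tab <- rbind(fit_tab, data.frame(
          experiment = bundles[[e]]$meta$experiment_id,
          mouse = bundles[[e]]$meta$mouse_id, variable = v,
          variant = "normalized", amplitude = NA_real_, tau = f$tau,
          sse = f$sse, r2 = f$r2,
          retained = is.finite(f$sse) && f$sse <= 1.6 && f$r2 > 0))
      }
    }
  }

  # pooled estimate per variable: the median time constant over retained
  # per-experiment fits (SSE <= 1.6 and R2 > 0, the standard fit filter)
  pooled_fit <- NULL
  for (v in .VARIABLES) {
    sub <- if (is.null(fit_tab)) NULL
           else fit_tab[fit_tab$variable == v & fit_tab$retained, , drop = FALSE]
    pooled_fit <- rbind(pooled_fit, data.frame(
      variable = v,
      tau = if (!is.null(sub) && nrow(sub)) median(sub$tau) else NA_real_,
      n_fits = if (is.null(sub)) 0L else nrow(sub)))
  }

  # LME on rankit-transformed per-experiment time constants
  lme_summary <- NULL
  fits_kept <- if (!is.null(fit_tab)) filter_fits(fit_tab) else NULL
  if (!is.null(fits_kept) && nrow(fits_kept) >= 4L &&
      length(unique(fits_kept$variable)) >= 2L) {
    rk <- rankit(fits_kept$tau)$transformed
    lme_summary <- tryCatch(
      lme_compare(rk, fits_kept$variable, fits_kept$mouse,
                  fits_kept$experiment)$pairwise,
      error = function(e) NULL)
  }

  cfg_hash <- config_hash(config)
  out <- list(
    session_inclusion = session_tab,
    qc = qc_tab,
    preference_fractions = pref_tab,
    cc_decay_fits = cc_fit_tab,
    encoding_calls = encoding_tab,
    decoding_curves = curve_tab,
    np_by_day = np_tab,
    decay_fits = fit_tab,
    pooled_decay_fits = pooled_fit,
    lme_summary = lme_summary,
    master_seed = seed,
    config_hash = cfg_hash
  )
  class(out) <- "report_bundle"
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

# stable hash of the config via serialization + md5
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2L)
  unname(tools::md5sum(tf))
}

#' Write a report bundle to disk
#'
#' Writes every table as CSV (plus the LME summary and run metadata as
#' JSON) and a manifest listing file names, sizes and md5 checksums.
#' Tables absent from the bundle are marked absent in the manifest rather
#' than failing.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  tables <- c("session_inclusion", "qc", "preference_fractions",
              "cc_decay_fits", "encoding_calls", "decoding_curves",
              "np_by_day", "decay_fits", "pooled_decay_fits", "lme_summary")
  manifest <- NULL
  for (nm in tables) {
    tab <- bundle[[nm]]
    f <- file.path(outdir, paste0(nm, ".csv"))
    if (is.null(tab)) {
      manifest <- rbind(manifest, data.frame(
        file = basename(f), present = FALSE, bytes = 0L,
        md5 = NA_character_))
      next
    }
    tab$master_seed <- bundle$master_seed
    tab$config_hash <- bundle$config_hash
    write.csv(tab, f, row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      file = basename(f), present = TRUE, bytes = file.size(f),
      md5 = unname(tools::md5sum(f))))
  }
  meta <- list(master_seed = bundle$master_seed,
               config_hash = bundle$config_hash,
               schema_version = "1")
  jsonlite::write_json(meta, file.path(outdir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle (seed", x$master_seed, ")\n")
  for (nm in setdiff(names(x), c("master_seed", "config_hash")))
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "absent"
                else paste0(nrow(x[[nm]]), " rows")))
  invisible(x)
}
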