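# The benchmark harness: methods x time windows x lead subsets x repeats,
# each cell a fresh stratified 9:1 split, fitted and scored on the held-out
# trials; long-format results, mean +/- sd aggregation and paired p-value
# tables.

GRID_METHODS <- c("cca", "fbcca", "cca_svm", "cca_gnb", "cnn", "cbam_cnn")

#' Experiment-grid specification
#'
#' @param methods subset of `"cca"`, `"fbcca"`, `"cca_svm"`, `"cca_gnb"`,
#'   `"cnn"`, `"cbam_cnn"`.
#' @param windows_s analysis window lengths in seconds.
#' @param lead_subsets named list of lead-name vectors; defaults to the three
#'   montage subsets O2 / O1+O2+P3 / all seven occipito-parietal leads.
#' @param n_repeats repeated splits per cell; repeat seeds are derived
#'   deterministically from `base_seed`.
#' @param base_seed integer master seed.
#' @param target_fs decimation target before filtering (Hz).
#' @param gaze_shift_s extra per-selection time added to the window length in
#'   the ITR (default 0: the ITR is reported against the analysis window
#'   alone).
#' @return an `experiment_grid` object.
#' @export
experiment_grid <- function(methods = GRID_METHODS,
                            windows_s = c(0.1, 0.5, 1, 1.5, 2),
                            lead_subsets = list(
                              `1` = "O2",
                              `3` = c("O1", "O2", "P3"),
                              `7` = c("O1", "O2", "P3", "P4", "PZ", "P7", "P8")),
                            n_repeats = 10L, base_seed = 1L,
                            target_fs = 500, gaze_shift_s = 0) {
  bad <- setdiff(methods, GRID_METHODS)
  if (length(bad)) abort_valid(sprintf("unknown method(s): %s", paste(bad, collapse = ", ")))
  if (!length(methods) || !length(windows_s) || !length(lead_subsets) || n_repeats < 1)
    abort_valid("grid axes must be non-empty")
  structure(list(methods = methods, windows_s = as.numeric(windows_s),
                 lead_subsets = lead_subsets, n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed), target_fs = target_fs,
                 gaze_shift_s = gaze_shift_s),
            class = "experiment_grid")
}

# Evaluate one method on one prepared cell; returns predicted frequencies.
run_cell_method <- function(method, tr_stack, te_stack, refs, w_fb, seed,
                            train_cfg) {
  nb <- dim(tr_stack$data)[2L]
  wide_band <- nb  # last bank band (7-50 Hz) carries the full usable spectrum
  trial_mat <- function(stack, i, band) {
    x <- stack$data[i, band, , , drop = FALSE]
    dim(x) <- dim(stack$data)[3:4]
    x
  }
  n_te <- n_trials(te_stack)
  if (method == "cca") {
    vapply(seq_len(n_te), function(i)
      cca_classify(trial_mat(te_stack, i, wide_band), refs), 0)
  } else if (method == "fbcca") {
    vapply(seq_len(n_te), function(i) {
      bt <- lapply(seq_len(nb), function(b) trial_mat(te_stack, i, b))
      refs$freqs[which.max(fbcca_scores(bt, refs, w_fb))]
    }, 0)
  } else if (method %in% c("cca_svm", "cca_gnb")) {
    feat <- function(stack) t(vapply(seq_len(n_trials(stack)), function(i)
      cca_features(trial_mat(stack, i, wide_band), refs),
      numeric(length(refs$freqs))))
    clf <- fit_feature_classifier(feat(tr_stack), tr_stack$labels,
                                  if (method == "cca_svm") "svm_linear" else "gnb")
    predict_features(clf, feat(te_stack))
  } else {
    spec <- model_spec(n_leads = dim(tr_stack$data)[3L],
                       window_samples = dim(tr_stack$data)[4L],
                       n_bands = nb, n_classes = length(te_stack$freq_set))
    mdl <- build_cbam_cnn(spec, seed = seed, cbam = (method == "cbam_cnn"))
    cfg <- train_cfg
    cfg$seed <- seed
    mdl <- train_network(mdl, tr_stack, cfg)
    predict(mdl, te_stack)$labels
  }
}

#' Run the full benchmark grid
#'
#' For every (method, window, lead subset, repeat) cell: decimate, restrict
#' leads, filter-bank decompose the full epochs (windows are cropped from the
#' filtered signal, avoiding per-window edge transients), draw a fresh
#' stratified 9:1 split, fit or train, and score the held-out trials. A cell
#' failure is logged and skipped, never aborting the grid. Rerunning with the
#' same grid and data reproduces every row.
#'
#' @param es an [epoch_set()] at the native sampling rate.
#' @param grid an [experiment_grid()].
#' @param train_cfg a [train_config()] for the network methods (the per-cell
#'   seed is overridden by the derived repeat seed).
#' @param bank a [filter_bank_spec()].
#' @param split_ratio train fraction (default 0.9 = 9:1).
#' @param ref_harmonics harmonics in the CCA reference set.
#' @param out_csv optional path; when given the long results table is written
#'   as CSV with fixed columns (method, window_s, n_leads, repeat, metric,
#'   value).
#' @return the long-format results `data.frame` (one row per cell metric),
#'   with failed cells recorded in `attr(, "failures")`.
#' @export
run_grid <- function(es, grid, train_cfg = train_config(), bank = filter_bank_spec(),
                     split_ratio = 0.9, ref_harmonics = 3L, out_csv = NULL) {
  stopifnot(inherits(es, "epoch_set"), inherits(grid, "experiment_grid"))
  es_d <- decimate_epochs(es, grid$target_fs)
  seeds <- derive_seeds(grid$base_seed, grid$n_repeats)
  rows <- list()
  failures <- character(0)
  freqs <- sort(es$freq_set)
  k <- length(freqs)
  for (ls_i in seq_along(grid$lead_subsets)) {
    leads <- grid$lead_subsets[[ls_i]]
    stack_full <- apply_filter_bank(select_leads(es_d, leads), bank)
    for (win in grid$windows_s) {
      stack_w <- crop_window(stack_full, win)
      refs <- make_references(freqs, H = ref_harmonics, window_s = win,
                              fs = grid$target_fs)
      w_fb <- fb_weights(length(bank$bands))
      for (rep_i in seq_len(grid$n_repeats)) {
        sp <- split_train_test(stack_w, ratio = split_ratio, seed = seeds[rep_i])
        for (method in grid$methods) {
          pred <- tryCatch(
            run_cell_method(method, sp$train, sp$test, refs, w_fb,
                            seeds[rep_i], train_cfg),
            error = function(e) {
              failures <<- c(failures, sprintf(
                "method=%s window=%g leads=%d repeat=%d: %s",
                method, win, length(leads), rep_i, conditionMessage(e)))
              NULL
            })
          if (is.null(pred)) next
          rep_true <- match(sp$test$labels, freqs)
          rep_pred <- match(pred, freqs)
          mr <- metrics_report(rep_true, rep_pred, k, win + grid$gaze_shift_s)
          rows[[length(rows) + 1L]] <- data.frame(
            method = method, window_s = win, n_leads = length(leads),
            repeat_ = rep_i,
            metric = c("accuracy", "macro_f1", "itr_bit_min",
                       "precision_macro", "recall_macro"),
            value = c(mr$accuracy, mr$macro_f1, mr$itr_bit_min,
                      mean(mr$precision), mean(mr$recall)))
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(0), window_s = numeric(0), n_leads = integer(0),
               repeat_ = integer(0), metric = character(0), value = numeric(0))
  names(out)[names(out) == "repeat_"] <- "repeat"
  attr(out, "failures") <- failures
  if (length(failures)) warning(sprintf("%d grid cell(s) failed and were skipped", length(failures)))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Aggregate long grid results to mean +/- sd cells
#'
#' @param results long table from [run_grid()].
#' @param metric which metric to tabulate.
#' @param digits decimals in the formatted cell.
#' @return a `data.frame` with one row per (method, n_leads) and one formatted
#'   `"mean +/- sd"` column per window, sd taken over repeats.
#' @export
aggregate_results <- function(results, metric = "accuracy", digits = 3L) {
  df <- results[results$metric == metric, , drop = FALSE]
  if (!nrow(df)) abort_valid(sprintf("no rows with metric '%s'", metric))
  agg_m <- stats::aggregate(value ~ method + n_leads + window_s, df, mean)
  agg_s <- stats::aggregate(value ~ method + n_leads + window_s, df, stats::sd)
  agg_m$cell <- sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                        agg_m$value, ifelse(is.na(agg_s$value), 0, agg_s$value))
  wide <- stats::reshape(agg_m[, c("method", "n_leads", "window_s", "cell")],
                         idvar = c("method", "n_leads"), timevar = "window_s",
                         direction = "wide")
  names(wide) <- sub("^cell\\.", "window_", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Paired p-values of a reference method against every other method
#'
#' Two-sided paired t-tests on per-repeat accuracies matched by split seed,
#' one row per (comparison method, window, lead count).
#'
#' @param results long table from [run_grid()].
#' @param reference reference method name (default `"cbam_cnn"`).
#' @param metric metric to compare.
#' @return `data.frame` with columns method, window_s, n_leads, p_value.
#' @export
pvalue_table <- function(results, reference = "cbam_cnn", metric = "accuracy") {
  df <- results[results$metric == metric, , drop = FALSE]
  out <- list()
  for (win in unique(df$window_s)) for (nl in unique(df$n_leads)) {
    sub <- df[df$window_s == win & df$n_leads == nl, , drop = FALSE]
    ref <- sub[sub$method == reference, ]
    ref <- ref[order(ref[["repeat"]]), ]
    if (!nrow(ref)) next
    for (m in setdiff(unique(sub$method), reference)) {
      cmp <- sub[sub$method == m, ]
      cmp <- cmp[order(cmp[["repeat"]]), ]
      if (nrow(cmp) != nrow(ref) || nrow(ref) < 3) next
      p <- suppressWarnings(paired_test(ref$value, cmp$value))
      out[[length(out) + 1L]] <- data.frame(method = m, window_s = win,
                                            n_leads = nl, p_value = p)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(method = character(0), window_s = numeric(0),
               n_leads = integer(0), p_value = numeric(0))
}
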