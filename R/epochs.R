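# The epoch container: labeled trial tensors shared by every module.

#' Construct an epoch set
#'
#' An `epoch_set` holds a stack of stimulus-locked EEG trials as a numeric
#' array of dimension trials x leads x samples (microvolts), together with the
#' sampling rate, ordered lead names, and the per-trial stimulus frequency
#' label in Hz.
#'
#' @param data numeric array, trials x leads x samples (a 0-trial array is
#'   allowed and yields an empty set).
#' @param fs sampling rate in Hz.
#' @param lead_names character vector naming the lead axis, in order.
#' @param labels numeric vector of per-trial stimulus frequencies (Hz).
#' @param freq_set the declared stimulus-frequency alphabet; all labels must be
#'   drawn from it. Defaults to the sorted unique labels.
#' @param provenance free-form metadata list (source, seed, window, ...).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, lead_names, labels, freq_set = NULL,
                      provenance = list()) {
  if (length(dim(data)) != 3L)
    abort_shape("epoch_set data must be a 3-axis array (trials x leads x samples)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    abort_valid("fs must be a single positive number")
  if (dim(data)[2L] != length(lead_names))
    abort_shape(sprintf("lead axis has extent %d but %d lead names were given",
                        dim(data)[2L], length(lead_names)))
  if (dim(data)[1L] != length(labels))
    abort_shape(sprintf("%d trials but %d labels", dim(data)[1L], length(labels)))
  freq_set <- freq_set %||% sort(unique(as.numeric(labels)))
  if (length(labels) && !all(labels %in% freq_set))
    abort_valid("labels contain frequencies outside the declared frequency set")
  structure(list(data = data, fs = as.numeric(fs),
                 lead_names = as.character(lead_names),
                 labels = as.numeric(labels),
                 freq_set = as.numeric(freq_set),
                 provenance = provenance),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d leads x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  if (d[1]) {
    tab <- table(factor(x$labels, levels = x$freq_set))
    cat("  trials per frequency:",
        paste(sprintf("%g Hz: %d", as.numeric(names(tab)), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of trials in an epoch container
#' @param x an `epoch_set` or `subband_stack`.
#' @return integer trial count.
#' @export
n_trials <- function(x) UseMethod("n_trials")

#' @export
n_trials.epoch_set <- function(x) dim(x$data)[1L]

#' @export
n_trials.subband_stack <- function(x) dim(x$data)[1L]

#' Subset trials of an epoch container
#'
#' @param x an `epoch_set` or `subband_stack`.
#' @param idx integer trial indices (kept in the given order).
#' @return an object of the same class restricted to the selected trials.
#' @export
subset_trials <- function(x, idx) UseMethod("subset_trials")

#' @export
subset_trials.epoch_set <- function(x, idx) {
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_trials(x)))
    abort_bounds("trial index out of range")
  x$data <- x$data[idx, , , drop = FALSE]
  x$labels <- x$labels[idx]
  x
}

#' @export
subset_trials.subband_stack <- function(x, idx) {
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_trials(x)))
    abort_bounds("trial index out of range")
  x$data <- x$data[idx, , , , drop = FALSE]
  x$labels <- x$labels[idx]
  x
}
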