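# Deterministic front end: decimation to 500 Hz, Butterworth filter-bank
# decomposition into subbands, lead selection, window cropping and the
# stratified train/test split.

#' Filter-bank specification
#'
#' The default bank is the four analysis subbands 7-16, 15-31, 23-46 and
#' 7-50 Hz: the first three track the first, second and third stimulus
#' harmonics, the last covers the whole usable SSVEP band (content above
#' 50 Hz is discarded as low-SNR).
#'
#' @param bands list of `c(low, high)` band edges in Hz.
#' @param order Butterworth order per band edge (the band-pass has `2*order`
#'   poles).
#' @param zero_phase apply each filter forward-backward (zero phase)?
#' @return a `filter_bank_spec` object.
#' @export
filter_bank_spec <- function(bands = list(c(7, 16), c(15, 31), c(23, 46), c(7, 50)),
                             order = 4L, zero_phase = TRUE) {
  if (!length(bands)) abort_valid("band list must be non-empty")
  for (b in bands) {
    if (length(b) != 2L || b[1] <= 0 || b[1] >= b[2])
      abort_valid(sprintf("invalid band (%s): need 0 < low < high",
                          paste(b, collapse = ", ")))
  }
  structure(list(bands = lapply(bands, as.numeric), order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_bank_spec")
}

#' Design a band-pass Butterworth filter
#'
#' @param low,high band edges in Hz (0 < low < high < fs/2).
#' @param fs sampling rate in Hz.
#' @param order filter order per edge.
#' @return a `signal::Arma`-style list with coefficients `b`, `a`; the design
#'   is checked for stability (all poles strictly inside the unit circle).
#' @export
design_bandpass <- function(low, high, fs, order = 4L) {
  if (low >= high) abort_valid(sprintf("low edge %g Hz must be below high edge %g Hz", low, high))
  if (low <= 0 || high >= fs / 2)
    abort_valid(sprintf("band (%g, %g) Hz invalid for fs = %g Hz", low, high, fs))
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  poles <- polyroot(rev(flt$a))
  if (any(Mod(poles) >= 1 - 1e-10))
    ssvepr_error("filter_error",
                 sprintf("unstable Butterworth design for band (%g, %g) Hz at order %d; reduce the order or use a second-order-sections form",
                         low, high, order))
  flt
}

# Zero-phase filtering with odd-reflection end padding, which suppresses the
# start/end transients of plain forward-backward filtering.
filtfilt_pad <- function(flt, x) {
  np <- min(12L * (max(length(flt$a), length(flt$b)) - 1L),
            length(x) - 1L)
  if (np < 1L) return(signal::filtfilt(flt, x))
  head_pad <- 2 * x[1L] - x[(np + 1L):2L]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - np)]
  y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
  y[(np + 1L):(np + length(x))]
}

filt_rows <- function(x, flt, zero_phase) {
  # x: leads x samples; filter along time
  out <- x
  for (l in seq_len(nrow(x))) {
    out[l, ] <- if (zero_phase) filtfilt_pad(flt, x[l, ])
                else signal::filter(flt, x[l, ])
  }
  out
}

#' Decimate an epoch set to a lower sampling rate
#'
#' Applies a zero-phase anti-aliasing low-pass (8th-order Butterworth at 80%
#' of the target Nyquist rate) before index decimation. The source rate must
#' be an integer multiple of the target.
#'
#' @param es an [epoch_set()].
#' @param target_fs target sampling rate in Hz (default 500).
#' @return the decimated [epoch_set()].
#' @export
decimate_epochs <- function(es, target_fs = 500) {
  stopifnot(inherits(es, "epoch_set"))
  ratio <- es$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    abort_valid(sprintf("source rate %g Hz is not an integer multiple of %g Hz; resample instead of decimating",
                        es$fs, target_fs))
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(es)
  lp <- signal::butter(8, 0.8 / ratio, type = "low")
  d <- dim(es$data)
  n_out <- d[3L] %/% ratio
  keep <- seq(1L, by = ratio, length.out = n_out)
  out <- array(0, dim = c(d[1L], d[2L], n_out))
  for (tr in seq_len(d[1L])) {
    for (l in seq_len(d[2L])) {
      y <- filtfilt_pad(lp, es$data[tr, l, ])
      out[tr, l, ] <- y[keep]
    }
  }
  es$data <- out
  es$fs <- target_fs
  es
}

#' Decompose an epoch set into filter-bank subbands
#'
#' Each trial is band-pass filtered once per band of the bank (zero-phase
#' forward-backward Butterworth by default), yielding a `subband_stack` with
#' data axis trials x bands x leads x samples. The input is unmodified.
#'
#' @param es an [epoch_set()].
#' @param spec a [filter_bank_spec()].
#' @return a `subband_stack`.
#' @export
apply_filter_bank <- function(es, spec = filter_bank_spec()) {
  stopifnot(inherits(es, "epoch_set"), inherits(spec, "filter_bank_spec"))
  d <- dim(es$data)
  nb <- length(spec$bands)
  filters <- vector("list", nb)
  for (bi in seq_len(nb)) {
    b <- spec$bands[[bi]]
    filters[[bi]] <- tryCatch(design_bandpass(b[1], b[2], es$fs, spec$order),
      error = function(e) ssvepr_error("filter_error",
        sprintf("band %d (%g-%g Hz): %s", bi, b[1], b[2], conditionMessage(e))))
  }
  out <- array(0, dim = c(d[1L], nb, d[2L], d[3L]))
  for (tr in seq_len(d[1L])) {
    x <- es$data[tr, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[2L])
    for (bi in seq_len(nb))
      out[tr, bi, , ] <- filt_rows(x, filters[[bi]], spec$zero_phase)
  }
  structure(list(data = out, band_spec = spec, fs = es$fs,
                 lead_names = es$lead_names, labels = es$labels,
                 freq_set = es$freq_set),
            class = "subband_stack")
}

#' @export
print.subband_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<subband_stack> %d trials x %d bands x %d leads x %d samples @ %g Hz\n",
              d[1], d[2], d[3], d[4], x$fs))
  invisible(x)
}

#' Restrict an epoch set to a subset of leads
#'
#' @param es an [epoch_set()].
#' @param subset lead names to keep, in the requested order.
#' @return the restricted [epoch_set()].
#' @export
select_leads <- function(es, subset) {
  stopifnot(inherits(es, "epoch_set"))
  idx <- match(subset, es$lead_names)
  if (anyNA(idx))
    abort_lead(sprintf("lead(s) not found: %s; available: %s",
                       paste(subset[is.na(idx)], collapse = ", "),
                       paste(es$lead_names, collapse = ", ")))
  es$data <- es$data[, idx, , drop = FALSE]
  es$lead_names <- es$lead_names[idx]
  es
}

#' Crop trials to an analysis time window
#'
#' Restricts every trial to samples `[offset_s, offset_s + window_s)` relative
#' to trial start. Works on an [epoch_set()] or a `subband_stack`.
#'
#' @param x an `epoch_set` or `subband_stack`.
#' @param window_s window length in seconds.
#' @param offset_s window start relative to stimulation onset (default 0).
#' @return an object of the same class with `round(window_s * fs)` samples.
#' @export
crop_window <- function(x, window_s, offset_s = 0) UseMethod("crop_window")

crop_idx <- function(n_samp, fs, window_s, offset_s) {
  n_w <- round(window_s * fs)
  i0 <- round(offset_s * fs)
  if (n_w < 1L) abort_valid("window_s must cover at least one sample")
  if (i0 < 0 || i0 + n_w > n_samp)
    abort_bounds(sprintf("window [%g, %g) s exceeds the %g s trial",
                         offset_s, offset_s + window_s, n_samp / fs))
  seq.int(i0 + 1L, i0 + n_w)
}

#' @export
crop_window.epoch_set <- function(x, window_s, offset_s = 0) {
  idx <- crop_idx(dim(x$data)[3L], x$fs, window_s, offset_s)
  x$data <- x$data[, , idx, drop = FALSE]
  x
}

#' @export
crop_window.subband_stack <- function(x, window_s, offset_s = 0) {
  idx <- crop_idx(dim(x$data)[4L], x$fs, window_s, offset_s)
  x$data <- x$data[, , , idx, drop = FALSE]
  x
}

#' Split trials into training and test partitions
#'
#' Deterministic given `seed`. With `stratified = TRUE` (default) the split is
#' performed per class, preserving class proportions to within one trial; a
#' 9:1 split of the default 160-trial set yields 144 training and 16 test
#' trials, 4 test trials per frequency.
#'
#' @param es an `epoch_set` (or `subband_stack`).
#' @param ratio train fraction in (0, 1]; `0.9` means 9:1.
#' @param seed integer seed for the partition.
#' @param stratified split within each class?
#' @return list with elements `train`, `test` (same class as `es`) and the
#'   index vectors `train_idx`, `test_idx` (disjoint, exhaustive).
#' @export
split_train_test <- function(es, ratio = 0.9, seed = 1L, stratified = TRUE) {
  n <- n_trials(es)
  if (ratio <= 0 || ratio > 1) abort_valid("ratio must be in (0, 1]")
  labels <- es$labels
  train_idx <- integer(0)
  if (stratified) {
    for (f in unique(labels)) {
      cls <- which(labels == f)
      n_tr <- round(ratio * length(cls))
      if (ratio < 1 && (n_tr == 0L || n_tr == length(cls)))
        abort_valid(sprintf("ratio %g leaves an empty partition for class %g Hz (%d trials)",
                            ratio, f, length(cls)))
      train_idx <- c(train_idx, with_seed(seed + round(f * 1000),
                                          sample(cls, n_tr)))
    }
    train_idx <- sort(train_idx)
  } else {
    n_tr <- round(ratio * n)
    if (ratio < 1 && (n_tr == 0L || n_tr == n))
      abort_valid(sprintf("ratio %g leaves an empty partition (%d trials)", ratio, n))
    train_idx <- sort(with_seed(seed, sample.int(n, n_tr)))
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_trials(es, train_idx),
       test = subset_trials(es, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}
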