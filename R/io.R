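# EDF/EDF+ reading, epoching of continuous recordings, and the on-disk epoch
# container. The EDF parser is deliberately minimal: int16 data records with
# per-signal physical scaling, plus EDF+ time-stamped annotation lists (TALs)
# mapped to events.

read_edf_str <- function(raw, from, len) {
  trimws(rawToChar(raw[from:(from + len - 1L)]))
}

read_edf_num <- function(raw, from, len, field) {
  s <- read_edf_str(raw, from, len)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) abort_format(sprintf("malformed EDF header field '%s': '%s'", field, s))
  v
}

#' Read a continuous EEG recording from an EDF/EDF+ file
#'
#' Loads all ordinary signals at their native rate, converts digital values to
#' physical units via the header's physical/digital ranges, and maps any
#' "EDF Annotations" signal to an event table (sample index + label). All data
#' signals must share one sampling rate.
#'
#' @param path path to an EDF or EDF+ file.
#' @return an object of class `eeg_recording`: list with `data`
#'   (leads x samples, physical units), `fs`, `lead_names`, and `events`
#'   (data.frame with columns `sample`, `label`, ascending).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("no such file: %s", path))
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) abort_format("EDF header truncated (file shorter than 256 bytes)")
  n_rec <- read_edf_num(hdr, 237L, 8L, "number of data records")
  rec_dur <- read_edf_num(hdr, 245L, 8L, "duration of a data record")
  ns <- as.integer(read_edf_num(hdr, 253L, 4L, "number of signals"))
  if (ns < 1L) abort_format("EDF header declares no signals")
  shdr <- readBin(con, "raw", 256L * ns)
  if (length(shdr) < 256L * ns) abort_format("EDF signal header truncated")
  fld <- function(width, offset) {
    vapply(seq_len(ns), function(i)
      read_edf_str(shdr, offset * ns + (i - 1L) * width + 1L, width), "")
  }
  labels <- fld(16L, 0L)
  # byte offsets of the per-signal field blocks within the signal header
  off <- c(label = 0L, transducer = 16L * ns, dim = 96L * ns, pmin = 104L * ns,
           pmax = 112L * ns, dmin = 120L * ns, dmax = 128L * ns,
           prefilter = 136L * ns, nsamp = 216L * ns)
  numfld <- function(o, w, name) vapply(seq_len(ns), function(i) {
    read_edf_num(shdr, o + (i - 1L) * w + 1L, w, sprintf("%s[%d]", name, i))
  }, 0)
  pmin <- numfld(off["pmin"], 8L, "physical minimum")
  pmax <- numfld(off["pmax"], 8L, "physical maximum")
  dmin <- numfld(off["dmin"], 8L, "digital minimum")
  dmax <- numfld(off["dmax"], 8L, "digital maximum")
  nsamp <- as.integer(numfld(off["nsamp"], 8L, "samples per record"))
  is_ann <- labels == "EDF Annotations"
  if (n_rec < 0) {  # -1 allowed by the standard: infer from file size
    rec_bytes <- sum(nsamp) * 2L
    n_rec <- floor((sz - 256L * (ns + 1L)) / rec_bytes)
  }
  n_rec <- as.integer(n_rec)
  data_idx <- which(!is_ann)
  if (!length(data_idx)) abort_format("EDF file contains no data signals")
  fs_all <- nsamp[data_idx] / rec_dur
  if (length(unique(fs_all)) != 1L)
    abort_format("data signals have differing sampling rates; mixed-rate EDF is unsupported")
  fs <- fs_all[1L]
  dat <- lapply(data_idx, function(i) numeric(n_rec * nsamp[i]))
  names(dat) <- as.character(data_idx)
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2L * nsamp[i]))
      } else {
        v <- readBin(con, "integer", nsamp[i], size = 2L, signed = TRUE,
                     endian = "little")
        if (length(v) < nsamp[i]) abort_format("EDF data records truncated")
        sc <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
        dat[[as.character(i)]][((r - 1L) * nsamp[i] + 1L):(r * nsamp[i])] <-
          (v - dmin[i]) * sc + pmin[i]
      }
    }
  }
  data <- do.call(rbind, dat)
  rownames(data) <- labels[data_idx]
  events <- parse_edf_annotations(ann_raw, fs)
  structure(list(data = data, fs = fs, lead_names = labels[data_idx],
                 events = events),
            class = "eeg_recording")
}

# EDF+ time-stamped annotation lists: each TAL is
# "onset[\x15duration]\x14label\x14[label\x14...]" and is terminated by \x00.
parse_edf_annotations <- function(ann_raw, fs) {
  ev <- data.frame(sample = integer(0), label = character(0))
  if (!length(ann_raw)) return(ev)
  nz <- which(ann_raw != as.raw(0))
  if (!length(nz)) return(ev)
  # contiguous non-NUL runs are individual TALs
  run_start <- nz[c(TRUE, diff(nz) > 1L)]
  run_end <- nz[c(diff(nz) > 1L, TRUE)]
  for (i in seq_along(run_start)) {
    tal <- rawToChar(ann_raw[run_start[i]:run_end[i]])
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(sub("\x15.*$", "", parts[1L])))
    if (is.na(onset)) next
    labels <- parts[-1L]
    labels <- labels[nzchar(labels)]
    for (lab in labels)
      ev <- rbind(ev, data.frame(sample = as.integer(round(onset * fs)) + 1L,
                                 label = lab))
  }
  ev <- ev[order(ev$sample), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One trial is extracted per labeled event, spanning samples
#' `[event, event + post_s * fs)`. Event labels are mapped to stimulus
#' frequencies through `label_map`.
#'
#' @param rec an `eeg_recording` from [read_edf()].
#' @param post_s epoch length after the event, in seconds.
#' @param label_map named numeric vector mapping event labels to stimulus
#'   frequencies in Hz; events with labels absent from the map are ignored.
#' @return an [epoch_set()].
#' @export
epoch_recording <- function(rec, post_s, label_map) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_post <- round(post_s * rec$fs)
  ev <- rec$events[rec$events$label %in% names(label_map), , drop = FALSE]
  n_tot <- ncol(rec$data)
  nl <- nrow(rec$data)
  data <- array(0, dim = c(nrow(ev), nl, n_post))
  labels <- numeric(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    s0 <- ev$sample[k]
    if (s0 + n_post - 1L > n_tot)
      abort_bounds(sprintf("event %d at sample %d: window of %d samples exceeds recording length %d",
                           k, s0, n_post, n_tot))
    data[k, , ] <- rec$data[, s0:(s0 + n_post - 1L)]
    labels[k] <- label_map[[ev$label[k]]]
  }
  epoch_set(data, rec$fs, rec$lead_names, labels,
            freq_set = sort(unique(as.numeric(label_map))),
            provenance = list(source = "edf", post_s = post_s))
}

CONTAINER_LAYOUT_VERSION <- 1L

#' Write an epoch set to disk
#'
#' The container is a versioned serialized bundle with a fixed layout:
#' fields `data` (trials x leads x samples), `labels`, `lead_names`, `fs`,
#' `freq_set`, `provenance` and `layout_version`. [read_epochs()] round-trips
#' it losslessly.
#'
#' @param es an [epoch_set()].
#' @param path output path (conventionally `.epochs.rds`).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  obj <- list(layout_version = CONTAINER_LAYOUT_VERSION, data = es$data,
              labels = es$labels, lead_names = es$lead_names, fs = es$fs,
              freq_set = es$freq_set, provenance = es$provenance)
  saveRDS(obj, path)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#' @param path container path.
#' @return an [epoch_set()].
#' @export
read_epochs <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    abort_format(sprintf("not a readable epoch container: %s", conditionMessage(e))))
  if (!is.list(obj) || is.null(obj$layout_version))
    abort_format("epoch container missing layout_version")
  if (obj$layout_version != CONTAINER_LAYOUT_VERSION)
    abort_format(sprintf("epoch container layout version %s; this build reads version %d",
                         obj$layout_version, CONTAINER_LAYOUT_VERSION))
  for (f in c("data", "labels", "lead_names", "fs"))
    if (is.null(obj[[f]]))
      abort_format(sprintf("epoch container missing required field '%s'", f))
  epoch_set(obj$data, obj$fs, obj$lead_names, obj$labels,
            freq_set = obj$freq_set, provenance = obj$provenance %||% list())
}
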