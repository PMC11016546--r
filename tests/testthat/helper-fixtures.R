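# Fixtures built in code at test time: a minimal EDF/EDF+ writer (16-bit data
# records plus an annotation signal), small epoch sets and subband stacks.

pad_field <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) stop("EDF field too long: ", s)
  formatC(s, width = -width)
}

# data: leads x samples (physical units); annotations: data.frame(onset_s, label).
write_edf_fixture <- function(path, data, fs, lead_names,
                              annotations = NULL) {
  n <- ncol(data)
  stopifnot(n %% fs == 0)
  n_rec <- n %/% fs
  nd <- nrow(data)
  has_ann <- !is.null(annotations)
  ns <- nd + as.integer(has_ann)
  ann_len <- 64L  # int16 samples per record reserved for the annotation signal
  pm <- pmax(apply(abs(data), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("test patient", 80), pad_field("test recording", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256L * (ns + 1L), 8),
    pad_field(if (has_ann) "EDF+C" else "", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeBin(charToRaw(hdr), con)
  sig_field <- function(vals, width) paste(vapply(vals, pad_field, "", width = width),
                                           collapse = "")
  labels <- c(lead_names, if (has_ann) "EDF Annotations")
  writeBin(charToRaw(paste0(
    sig_field(labels, 16),
    sig_field(rep("", ns), 80),
    sig_field(c(rep("uV", nd), if (has_ann) ""), 8),
    sig_field(c(sprintf("%.4f", -pm), if (has_ann) "-1"), 8),
    sig_field(c(sprintf("%.4f", pm), if (has_ann) "1"), 8),
    sig_field(rep("-32767", ns), 8),
    sig_field(rep("32767", ns), 8),
    sig_field(rep("", ns), 80),
    sig_field(c(rep(fs, nd), if (has_ann) ann_len), 8),
    sig_field(rep("", ns), 32))), con)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (l in seq_len(nd)) {
      dig <- as.integer(round(data[l, cols] / pm[l] * 32767))
      writeBin(dig, con, size = 2L, endian = "little")
    }
    if (has_ann) {
      tal <- c(charToRaw(sprintf("+%d\x14\x14", r - 1L)), as.raw(0))
      in_rec <- annotations[annotations$onset_s >= r - 1 & annotations$onset_s < r, ,
                            drop = FALSE]
      for (i in seq_len(nrow(in_rec)))
        tal <- c(tal, charToRaw(sprintf("+%.4f\x14%s\x14", in_rec$onset_s[i],
                                        in_rec$label[i])), as.raw(0))
      if (length(tal) > 2L * ann_len) stop("annotation record overflow")
      writeBin(c(tal, raw(2L * ann_len - length(tal))), con)
    }
  }
  invisible(path)
}

# Small labeled epoch set with random content.
fake_epochs <- function(n = 8, leads = c("O1", "O2"), samples = 100, fs = 100,
                        freqs = c(8, 10), seed = 1) {
  set.seed(seed)
  labels <- rep(freqs, length.out = n)
  epoch_set(array(rnorm(n * length(leads) * samples),
                  c(n, length(leads), samples)),
            fs, leads, labels, freq_set = freqs)
}

# Small subband stack with random content (bypasses filtering).
fake_stack <- function(n = 8, bands = 4, leads = 3, samples = 40, fs = 100,
                       freqs = c(8, 10, 12, 15), seed = 1) {
  set.seed(seed)
  structure(list(
    data = array(rnorm(n * bands * leads * samples), c(n, bands, leads, samples)),
    band_spec = NULL, fs = fs,
    lead_names = paste0("L", seq_len(leads)),
    labels = rep(freqs, length.out = n),
    freq_set = freqs), class = "subband_stack")
}

# A small network spec that trains in well under a second.
tiny_spec <- function(samples = 24, leads = 3, bands = 2, classes = 3) {
  model_spec(n_leads = leads, window_samples = samples, n_bands = bands,
             n_classes = classes, k1 = 4, k2 = 4, k3 = 4, k4 = 6,
             conv2_kernel = 5, conv3_kernel = 3, conv4_kernel = 3,
             rho = 2, z_spatial = 3)
}

expect_equal_tol <- function(a, b, tol = 1e-9) testthat::expect_lt(max(abs(a - b)), tol)
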