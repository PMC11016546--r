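# Synthetic SSVEP generator: stimulus-locked sinusoids + harmonics over an
# occipito-parietal montage, with white or 1/f background noise calibrated to
# an in-band SNR. Stands in for real recordings so the whole pipeline is
# exercisable offline.

#' Simulation configuration for synthetic SSVEP epochs
#'
#' Defaults emulate a 4-target flicker experiment on a 7-lead occipito-parietal
#' montage: stimulation frequencies 8/10/12/15 Hz, 3 s of stimulation sampled
#' at 1000 Hz, 40 trials per frequency (160 trials in total).
#'
#' @param stim_freqs distinct stimulation frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param duration_s trial length in seconds.
#' @param n_trials_per_class trials generated per stimulation frequency.
#' @param leads ordered lead names.
#' @param harmonic_amps relative amplitude of harmonic orders 1..H. The default
#'   `c(1, 0.5, 0.25)` gives the 1/2-per-order decay typical of occipital SSVEP
#'   spectra.
#' @param lead_gains per-lead multiplicative gain on the SSVEP component;
#'   occipital leads (O1, O2) default to 1.0 and parietal leads to 0.6,
#'   a simple gradient standing in for the unspecified scalp topography.
#' @param snr_db target in-band (7-50 Hz) signal-to-noise ratio in dB on a
#'   unit-gain lead; `Inf` disables noise.
#' @param noise_kind `"pink"` (1/f power, EEG-like; default) or `"white"`.
#' @param phase_mode `"fixed"` (stimulus phase 0 every trial) or `"random"`
#'   (uniform random fundamental phase per trial). Harmonic phases are locked
#'   to the fundamental (phi_h = h * phi_1) in both modes.
#' @param seed integer; the generated dataset is a pure function of the full
#'   configuration including this seed.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(stim_freqs = c(8, 10, 12, 15),
                       fs = 1000,
                       duration_s = 3,
                       n_trials_per_class = 40,
                       leads = c("O1", "O2", "P3", "P4", "PZ", "P7", "P8"),
                       harmonic_amps = c(1, 0.5, 0.25),
                       lead_gains = NULL,
                       snr_db = 0,
                       noise_kind = c("pink", "white"),
                       phase_mode = c("fixed", "random"),
                       seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  phase_mode <- match.arg(phase_mode)
  if (anyDuplicated(stim_freqs)) abort_valid("stim_freqs must be distinct")
  if (any(stim_freqs <= 0)) abort_valid("stim_freqs must be positive")
  if (fs <= 0 || duration_s <= 0) abort_valid("fs and duration_s must be positive")
  if (n_trials_per_class < 0) abort_valid("n_trials_per_class must be >= 0")
  if (any(harmonic_amps < 0)) abort_valid("harmonic_amps must be non-negative")
  if (is.null(lead_gains)) lead_gains <- ifelse(grepl("^O", leads), 1.0, 0.6)
  if (length(lead_gains) != length(leads))
    abort_valid("lead_gains must have one entry per lead")
  if (any(lead_gains <= 0)) abort_valid("lead_gains must be strictly positive")
  H <- length(harmonic_amps)
  bad <- outer(stim_freqs, seq_len(H)) >= fs / 2
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    abort_valid(sprintf("harmonic %d of %g Hz is at or above the Nyquist rate %g Hz",
                        ij[2L], stim_freqs[ij[1L]], fs / 2))
  }
  structure(list(stim_freqs = as.numeric(stim_freqs), fs = as.numeric(fs),
                 duration_s = as.numeric(duration_s),
                 n_trials_per_class = as.integer(n_trials_per_class),
                 leads = as.character(leads),
                 harmonic_amps = as.numeric(harmonic_amps),
                 lead_gains = as.numeric(lead_gains),
                 snr_db = as.numeric(snr_db), noise_kind = noise_kind,
                 phase_mode = phase_mode, seed = as.integer(seed)),
            class = "sim_config")
}

# Power of x within [lo, hi] Hz, computed from the discrete Fourier transform.
band_power <- function(x, fs, lo = 7, hi = 50) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  p <- Mod(stats::fft(x))^2 / n^2
  2 * sum(p[keep])
}

# Unit-variance noise of the requested spectral colour.
noise_vector <- function(n, kind) {
  if (kind == "white") return(stats::rnorm(n))
  # pink: shape a white spectrum by 1/sqrt(f) (power ~ 1/f), zero DC
  half <- floor(n / 2)
  mag <- c(0, 1 / sqrt(seq_len(half)))
  ph <- stats::runif(half + 1, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = ph)
  full <- complex(length.out = n)
  full[seq_len(half + 1)] <- spec
  if (n %% 2 == 0) full[half + 1] <- complex(real = Re(spec[half + 1]))
  idx <- seq(2, half + if (n %% 2 == 0) 0 else 1)
  full[n + 2 - idx] <- Conj(full[idx])
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

#' Generate one synthetic SSVEP trial
#'
#' Each lead carries `lead_gain * sum_h amp_h * sin(2*pi*h*f*t + h*phi_1)` plus
#' independent noise scaled so that the in-band (7-50 Hz) noise power on every
#' lead equals the unit-gain in-band signal power divided by `10^(snr_db/10)`.
#'
#' @param cfg a [sim_config()].
#' @param class_index index into `cfg$stim_freqs` (1-based).
#' @param seed integer seed for this trial's noise and random phase.
#' @return numeric matrix, leads x samples.
#' @export
generate_trial <- function(cfg, class_index, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (class_index < 1 || class_index > length(cfg$stim_freqs))
    abort_valid("class_index outside the configured frequency set")
  n <- round(cfg$duration_s * cfg$fs)
  f <- cfg$stim_freqs[class_index]
  tt <- (seq_len(n) - 1) / cfg$fs
  with_seed(seed, {
    phi1 <- if (cfg$phase_mode == "random") stats::runif(1, 0, 2 * pi) else 0
    s0 <- rep(0, n)
    for (h in seq_along(cfg$harmonic_amps))
      s0 <- s0 + cfg$harmonic_amps[h] * sin(2 * pi * h * f * tt + h * phi1)
    out <- outer(cfg$lead_gains, s0)
    if (is.finite(cfg$snr_db)) {
      p_sig <- band_power(s0, cfg$fs)
      p_target <- p_sig / 10^(cfg$snr_db / 10)
      for (l in seq_along(cfg$leads)) {
        nv <- noise_vector(n, cfg$noise_kind)
        p_nv <- band_power(nv, cfg$fs)
        out[l, ] <- out[l, ] + nv * sqrt(p_target / p_nv)
      }
    }
    dimnames(out) <- list(cfg$leads, NULL)
    out
  })
}

#' Generate a full labeled synthetic dataset
#'
#' Generates `n_trials_per_class` trials per stimulation frequency, attaches
#' the frequency labels, and shuffles trial order deterministically from
#' `cfg$seed`. Two calls with identical configurations produce byte-identical
#' epoch sets.
#'
#' @param cfg a [sim_config()].
#' @return an [epoch_set()] with provenance recording the configuration.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_cls <- length(cfg$stim_freqs)
  n_tr <- cfg$n_trials_per_class * n_cls
  n <- round(cfg$duration_s * cfg$fs)
  data <- array(0, dim = c(n_tr, length(cfg$leads), n))
  labels <- numeric(n_tr)
  if (n_tr > 0) {
    seeds <- derive_seeds(cfg$seed, n_tr + 1L)
    k <- 0L
    for (ci in seq_len(n_cls)) {
      for (r in seq_len(cfg$n_trials_per_class)) {
        k <- k + 1L
        data[k, , ] <- generate_trial(cfg, ci, seed = seeds[k])
        labels[k] <- cfg$stim_freqs[ci]
      }
    }
    ord <- with_seed(seeds[n_tr + 1L], sample.int(n_tr))
    data <- data[ord, , , drop = FALSE]
    labels <- labels[ord]
  }
  epoch_set(data, cfg$fs, cfg$leads, labels, freq_set = cfg$stim_freqs,
            provenance = list(source = "synthetic", seed = cfg$seed,
                              snr_db = cfg$snr_db, noise_kind = cfg$noise_kind,
                              phase_mode = cfg$phase_mode))
}
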