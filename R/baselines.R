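# Classical SSVEP recognizers: CCA against sin/cos reference sets, filter-bank
# CCA with n^(-a) + b band weights, and CCA-feature classifiers (linear SVM,
# Gaussian naive Bayes).

#' Sin/cos reference signals for CCA frequency recognition
#'
#' For each stimulation frequency `f` builds the matrix whose rows are
#' `sin(2*pi*h*f*t)` and `cos(2*pi*h*f*t)` for harmonic orders `h = 1..H`
#' over the analysis window (2H x T).
#'
#' @param freqs stimulation frequencies in Hz.
#' @param H number of harmonics (default 3, matching the harmonic-aligned
#'   subband design).
#' @param window_s window length in seconds.
#' @param fs sampling rate in Hz.
#' @return a `reference_set`: named list of 2H x T matrices plus metadata.
#' @export
make_references <- function(freqs, H = 3L, window_s, fs) {
  n <- round(window_s * fs)
  tt <- (seq_len(n) - 1) / fs
  refs <- lapply(freqs, function(f) {
    if (H * f >= fs / 2)
      abort_valid(sprintf("harmonic %d of %g Hz is at or above Nyquist (%g Hz)", H, f, fs / 2))
    Y <- matrix(0, 2L * H, n)
    for (h in seq_len(H)) {
      Y[2L * h - 1L, ] <- sin(2 * pi * h * f * tt)
      Y[2L * h, ] <- cos(2 * pi * h * f * tt)
    }
    Y
  })
  names(refs) <- as.character(freqs)
  structure(list(refs = refs, freqs = as.numeric(freqs), H = as.integer(H),
                 fs = as.numeric(fs), window_s = as.numeric(window_s)),
            class = "reference_set")
}

#' First canonical correlation between two multichannel signals
#'
#' Solves the canonical correlation generalized eigenproblem
#' `Cxy Cyy^-1 Cyx u = rho^2 Cxx u` after internally centering the rows, with
#' a relative ridge of 1e-8 on the auto-covariance diagonals so that
#' rank-deficient short windows remain solvable.
#'
#' @param X leads x T signal matrix.
#' @param Y reference matrix (e.g. 2H x T), same T.
#' @return the first canonical correlation, clamped to `[0, 1]`.
#' @export
cca_max_corr <- function(X, Y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(Y)) abort_shape("X and Y must have the same number of samples")
  Tn <- ncol(X)
  if (Tn <= max(nrow(X), nrow(Y)))
    warning("fewer samples than signal dimensions; canonical correlation is degenerate")
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  solve_rho <- function(reg) {
    Cxx <- tcrossprod(Xc) / Tn
    Cxx <- Cxx + diag(reg * mean(diag(Cxx)) + 1e-300, nrow(Cxx))
    Cyy <- tcrossprod(Yc) / Tn
    Cyy <- Cyy + diag(reg * mean(diag(Cyy)) + 1e-300, nrow(Cyy))
    Cxy <- tcrossprod(Xc, Yc) / Tn
    M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
    max(Re(eigen(M, only.values = TRUE)$values))
  }
  rho2 <- tryCatch(solve_rho(1e-10), error = function(e) {
    warning("rank-deficient covariance; falling back to a stronger regularized solve")
    solve_rho(1e-6)
  })
  sqrt(min(max(rho2, 0), 1))
}

#' Classify one trial by maximum canonical correlation
#'
#' Picks the stimulation frequency whose sin/cos reference attains the highest
#' first canonical correlation with the trial. Ties (including the all-zero
#' degenerate trial) break deterministically to the first frequency in the
#' reference set, with a warning for degenerate input.
#'
#' @param trial leads x T matrix.
#' @param refs a [make_references()] set with matching window length.
#' @return the winning frequency in Hz.
#' @export
cca_classify <- function(trial, refs) {
  stopifnot(inherits(refs, "reference_set"))
  if (is.null(dim(trial))) trial <- matrix(trial, nrow = 1)
  if (ncol(trial) != ncol(refs$refs[[1]]))
    abort_shape(sprintf("trial has %d samples but references have %d",
                        ncol(trial), ncol(refs$refs[[1]])))
  if (all(trial == 0)) {
    warning("all-zero trial; tie broken to the first reference frequency")
    return(refs$freqs[1L])
  }
  rho <- vapply(refs$refs, function(Y) cca_max_corr(trial, Y), 0)
  refs$freqs[which.max(rho)]
}

#' Per-frequency canonical-correlation feature vector
#'
#' @param trial leads x T matrix.
#' @param refs a [make_references()] set.
#' @return numeric vector of first canonical correlations, one per frequency,
#'   in the reference set's frequency order.
#' @export
cca_features <- function(trial, refs) {
  stopifnot(inherits(refs, "reference_set"))
  if (is.null(dim(trial))) trial <- matrix(trial, nrow = 1)
  vapply(refs$refs, function(Y) cca_max_corr(trial, Y), 0)
}

#' Filter-bank CCA band weights
#'
#' The standard decaying weight profile `w(n) = n^(-a) + b` over band index
#' `n = 1..n_bands`.
#'
#' @param n_bands number of bands.
#' @param a,b profile parameters (defaults 1.25 and 0.25, the values
#'   recommended for filter-bank CCA).
#' @return strictly positive numeric weight vector.
#' @export
fb_weights <- function(n_bands, a = 1.25, b = 0.25) {
  w <- seq_len(n_bands)^(-a) + b
  if (any(w <= 0)) abort_valid("filter-bank weights must be strictly positive")
  w
}

# Score table for one trial given a list of band-filtered copies of the trial.
fbcca_scores <- function(band_trials, refs, w) {
  sapply(seq_along(refs$refs), function(fi) {
    sum(vapply(seq_along(band_trials), function(n)
      w[n] * cca_max_corr(band_trials[[n]], refs$refs[[fi]])^2, 0))
  })
}

#' Classify one trial by filter-bank CCA
#'
#' The trial is decomposed by the filter bank; for each candidate frequency
#' the squared first canonical correlations of the band-filtered copies are
#' combined with weights `w(n)`, and the highest combined score wins.
#'
#' @param trial leads x T matrix at sampling rate `fs`.
#' @param refs a [make_references()] set.
#' @param bank a [filter_bank_spec()].
#' @param w band weights (default [fb_weights()] for the bank size).
#' @param fs sampling rate of `trial` (default the reference set's rate).
#' @return the winning frequency in Hz.
#' @export
fbcca_classify <- function(trial, refs, bank = filter_bank_spec(), w = NULL,
                           fs = refs$fs) {
  stopifnot(inherits(refs, "reference_set"))
  if (is.null(dim(trial))) trial <- matrix(trial, nrow = 1)
  w <- w %||% fb_weights(length(bank$bands))
  band_trials <- lapply(seq_along(bank$bands), function(bi) {
    b <- bank$bands[[bi]]
    flt <- design_bandpass(b[1], b[2], fs, bank$order)
    filt_rows(trial, flt, bank$zero_phase)
  })
  refs$freqs[which.max(fbcca_scores(band_trials, refs, w))]
}

#' Fit a classifier on CCA feature vectors
#'
#' @param features matrix, trials x features (per-frequency canonical
#'   correlations).
#' @param labels per-trial class labels (stimulus frequencies).
#' @param kind `"svm_linear"` (linear-kernel support vector machine) or
#'   `"gnb"` (Gaussian naive Bayes).
#' @return a `cca_feature_classifier`; predict with [predict_features()].
#' @export
fit_feature_classifier <- function(features, labels, kind = c("svm_linear", "gnb")) {
  kind <- match.arg(kind)
  if (length(unique(labels)) < 2) abort_valid("need at least 2 classes to fit a classifier")
  y <- factor(labels)
  fit <- if (kind == "svm_linear") {
    e1071::svm(x = as.matrix(features), y = y, kernel = "linear", scale = FALSE)
  } else {
    df <- as.data.frame(as.matrix(features))
    e1071::naiveBayes(x = df, y = y)
  }
  structure(list(kind = kind, fit = fit, levels = levels(y)), class = "cca_feature_classifier")
}

#' Predict labels from CCA feature vectors
#' @param clf a [fit_feature_classifier()] model.
#' @param features matrix, trials x features.
#' @return numeric vector of predicted stimulus frequencies.
#' @export
predict_features <- function(clf, features) {
  stopifnot(inherits(clf, "cca_feature_classifier"))
  features <- as.matrix(features)
  pred <- if (clf$kind == "svm_linear") {
    predict(clf$fit, features)
  } else {
    predict(clf$fit, as.data.frame(features))
  }
  as.numeric(as.character(pred))
}
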