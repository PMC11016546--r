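# CCA frequency recognition, filter-bank CCA, and CCA-feature classifiers.

# Independent oracle: first singular value of the whitened cross-covariance.
cca_oracle_svd <- function(X, Y) {
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / ncol(X); Cyy <- tcrossprod(Yc) / ncol(Y)
  Cxy <- tcrossprod(Xc, Yc) / ncol(X)
  isq <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), nrow(C)) %*% t(e$vectors)
  }
  svd(isq(Cxx) %*% Cxy %*% isq(Cyy))$d[1]
}

test_that("reference sets have the declared sin/cos structure", {
  refs <- make_references(c(8, 10, 12, 15), H = 3, window_s = 2, fs = 500)
  expect_length(refs$refs, 4)
  for (Y in refs$refs) expect_equal(dim(Y), c(6L, 1000L))
  one <- make_references(10, H = 1, window_s = 1, fs = 500)
  tt <- (0:499) / 500
  expect_equal(one$refs[["10"]][1, ], sin(2 * pi * 10 * tt))
  expect_equal(one$refs[["10"]][2, ], cos(2 * pi * 10 * tt))
  # integer-cycle windows: every row norm is sqrt(T/2) within 1%
  norms <- sqrt(rowSums(refs$refs[["8"]]^2))
  expect_true(all(abs(norms - sqrt(1000 / 2)) / sqrt(1000 / 2) < 0.01))
  expect_error(make_references(c(10, 200), H = 3, window_s = 1, fs = 500),
               class = "ssvepr_validation_error")
})

test_that("canonical correlation is 1 for self, 0 for orthogonal, and matches the SVD oracle", {
  refs <- make_references(10, H = 1, window_s = 1, fs = 500)
  Y <- refs$refs[["10"]]
  expect_gt(cca_max_corr(Y, Y), 1 - 1e-9)
  X_mix <- matrix(c(0.3, 0.7, -0.2, 0.5), 2) %*% Y  # inside span(Y)
  expect_gt(cca_max_corr(X_mix, Y), 1 - 1e-9)
  # 20 Hz sin/cos are exactly orthogonal to 10 Hz over an integer-cycle window
  X_orth <- make_references(20, H = 1, window_s = 1, fs = 500)$refs[["20"]]
  expect_lt(cca_max_corr(X_orth, Y), 1e-6)
  set.seed(21)
  for (i in 1:20) {
    X <- matrix(rnorm(7 * 250), 7)
    Yr <- matrix(rnorm(6 * 250), 6)
    expect_lt(abs(cca_max_corr(X, Yr) - cca_oracle_svd(X, Yr)), 1e-8)
    cc <- stats::cancor(t(X), t(Yr))$cor[1]
    expect_lt(abs(cca_max_corr(X, Yr) - cc), 1e-7)
  }
})

test_that("canonical correlation is invariant to lead mixing, row scaling, and argument order", {
  set.seed(22)
  X <- matrix(rnorm(5 * 300), 5)
  Y <- matrix(rnorm(4 * 300), 4)
  base <- cca_max_corr(X, Y)
  A <- matrix(rnorm(25), 5); while (abs(det(A)) < 1e-3) A <- matrix(rnorm(25), 5)
  expect_lt(abs(cca_max_corr(A %*% X, Y) - base), 1e-8)
  expect_lt(abs(cca_max_corr(X * 17.3, Y) - base), 1e-8)
  expect_lt(abs(cca_max_corr(Y, X) - base), 1e-8)
})

test_that("noise-free trials classify to their stimulus frequency; degenerate input warns", {
  cfg <- sim_config(snr_db = Inf, n_trials_per_class = 1, duration_s = 2, seed = 30)
  es <- decimate_epochs(generate_dataset(cfg), 500)
  refs <- make_references(sort(es$freq_set), H = 3, window_s = 2, fs = 500)
  for (i in seq_len(n_trials(es)))
    expect_equal(cca_classify(es$data[i, , ], refs), es$labels[i])
  expect_warning(lab <- cca_classify(matrix(0, 7, 1000), refs), "zero")
  expect_equal(lab, refs$freqs[1])
  expect_error(cca_classify(matrix(0, 7, 999), refs), class = "ssvepr_shape_error")
})

test_that("CCA features decompose into per-frequency correlations with the right argmax", {
  cfg <- sim_config(snr_db = Inf, n_trials_per_class = 1, duration_s = 1, seed = 31)
  es <- decimate_epochs(generate_dataset(cfg), 500)
  refs <- make_references(sort(es$freq_set), H = 3, window_s = 1, fs = 500)
  for (i in seq_len(n_trials(es))) {
    fv <- cca_features(es$data[i, , ], refs)
    expect_length(fv, 4)
    expect_true(all(fv >= 0 & fv <= 1))
    expect_equal(refs$freqs[which.max(fv)], es$labels[i])
    for (j in seq_along(refs$refs))
      expect_equal(fv[[j]], cca_max_corr(es$data[i, , ], refs$refs[[j]]))
  }
})

test_that("filter-bank CCA reduces to plain CCA for a single band", {
  cfg <- sim_config(snr_db = 0, n_trials_per_class = 2, duration_s = 1, seed = 32)
  es <- decimate_epochs(generate_dataset(cfg), 500)
  refs <- make_references(sort(es$freq_set), H = 3, window_s = 1, fs = 500)
  one_band <- filter_bank_spec(bands = list(c(7, 50)))
  bank <- filter_bank_spec()
  flt <- design_bandpass(7, 50, 500)
  for (i in seq_len(n_trials(es))) {
    tr <- es$data[i, , ]
    lab_fb <- fbcca_classify(tr, refs, one_band, w = 1)
    lab_cca <- cca_classify(ssvepr:::filt_rows(tr, flt, TRUE), refs)
    expect_equal(lab_fb, lab_cca)
  }
  expect_true(all(fb_weights(4) > 0))
  expect_equal(fb_weights(4), (1:4)^(-1.25) + 0.25)
})

test_that("with equal weights and energy in one band, that band decides the label", {
  refs <- make_references(c(8, 10, 12, 15), H = 3, window_s = 1, fs = 500)
  tt <- (0:499) / 500
  trial10 <- rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 10 * tt))
  # hand the scorer band-filtered copies directly: all energy in band 1
  bt <- list(trial10, trial10 * 0, trial10 * 0, trial10 * 0)
  sc <- ssvepr:::fbcca_scores(bt, refs, rep(1, 4))
  expect_equal(refs$freqs[which.max(sc)], 10)
})

test_that("feature classifiers fit and predict; degenerate inputs error or sit at chance", {
  set.seed(33)
  f1 <- cbind(rnorm(20, 5, 0.5), rnorm(20, 0))
  f2 <- cbind(rnorm(20, -5, 0.5), rnorm(20, 0))
  feats <- rbind(f1, f2)
  labs <- rep(c(8, 10), each = 20)
  svm <- fit_feature_classifier(feats, labs, "svm_linear")
  expect_equal(predict_features(svm, feats), labs)
  # equal class-conditional means: GNB cannot beat chance by much
  feats0 <- matrix(rnorm(400), 200)
  labs0 <- rep(c(8, 10), 100)
  gnb <- fit_feature_classifier(feats0, labs0, "gnb")
  expect_lt(mean(predict_features(gnb, feats0) == labs0), 0.7)
  expect_error(fit_feature_classifier(feats, rep(8, 40)),
               class = "ssvepr_validation_error")
})
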