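# Network construction, shape/parameter accounting, compiled-kernel
# equivalence, gradient correctness, determinism, and prediction purity.

# Closed-form parameter count from the declared layer shapes alone.
expected_n_params <- function(s, cbam = TRUE) {
  conv <- function(cout, fan_in) cout * fan_in + cout
  bn <- function(C) 2 * C
  cbam_ct <- function(C, rho, Z) {
    Ch <- C / rho
    (Ch * C + Ch) + (C * Ch + C) + (Z * Z * 2 + 1)
  }
  per_branch <- conv(s$k1, s$n_leads) + bn(s$k1) +
    conv(s$k2, s$k1 * s$conv2_kernel) + bn(s$k2) +
    conv(s$k3, s$k2 * s$conv3_kernel) + bn(s$k3) +
    if (cbam) cbam_ct(s$k3, s$rho, s$z_spatial) else 0
  Cf <- s$n_bands * s$k3
  s$n_bands * per_branch +
    (if (cbam) cbam_ct(Cf, s$rho, s$z_spatial) else 0) +
    conv(s$k4, Cf * s$conv4_kernel) + bn(s$k4) +
    conv(s$n_classes, s$k4 * s$window_samples)
}

test_that("parameter counts match the shape-arithmetic oracle; attention adds its closed form", {
  for (s in list(tiny_spec(), model_spec(n_leads = 7, window_samples = 1000))) {
    m <- build_cbam_cnn(s, seed = 1)
    p <- build_plain_cnn(s, seed = 1)
    expect_equal(n_params(m), expected_n_params(s, TRUE))
    expect_equal(n_params(p), expected_n_params(s, FALSE))
    expect_lt(n_params(p), n_params(m))
    expect_equal(n_params(m) - n_params(p),
                 expected_n_params(s, TRUE) - expected_n_params(s, FALSE))
  }
})

test_that("plain and attention models share non-attention initial weights at the same seed", {
  s <- tiny_spec()
  m <- build_cbam_cnn(s, seed = 7)
  p <- build_plain_cnn(s, seed = 7)
  for (nm in ssvepr:::active_param_names(p))
    expect_identical(m$params[[nm]], p$params[[nm]])
})

test_that("disabling the attention gates reduces the attention model to the plain model", {
  s <- tiny_spec()
  m <- build_cbam_cnn(s, seed = 3)
  p <- build_plain_cnn(s, seed = 3)
  set.seed(1)
  Xl <- lapply(seq_len(s$n_bands), function(b)
    array(rnorm(s$n_leads * s$window_samples * 3), c(s$n_leads, s$window_samples, 3)))
  m_gated_off <- m
  m_gated_off$cbam_enabled <- FALSE  # identity gates
  fa <- ssvepr:::net_forward(m_gated_off, Xl)
  fb <- ssvepr:::net_forward(p, Xl)
  expect_equal(fa$probs, fb$probs, tolerance = 1e-14)
  # and the true attention forward differs
  fc <- ssvepr:::net_forward(m, Xl)
  expect_false(isTRUE(all.equal(fc$probs, fb$probs)))
})

test_that("softmax head outputs normalized 4-class probabilities", {
  s <- model_spec(n_leads = 7, window_samples = 100)
  m <- build_cbam_cnn(s, seed = 2)
  set.seed(2)
  Xl <- lapply(1:4, function(b) array(rnorm(7 * 100 * 5), c(7, 100, 5)))
  pr <- ssvepr:::net_forward(m, Xl)$probs
  expect_equal(dim(pr), c(4L, 5L))
  expect_lt(max(abs(colSums(pr) - 1)), 1e-6)
})

test_that("compiled convolution kernels agree with the pure-R reference", {
  set.seed(20)
  C <- 5; Tn <- 19; B <- 3; K <- 7; Cout <- 4
  X <- matrix(rnorm(C * Tn * B), C, Tn * B)
  W <- matrix(rnorm(Cout * C * K), Cout, C * K)
  bv <- rnorm(Cout)
  a <- ssvepr:::conv_forward(X, W, bv, C, Tn, B, K)
  r <- ssvepr:::conv_forward_ref(X, W, bv, C, Tn, B, K)
  expect_equal(a$Y, r$Y, tolerance = 1e-12)
  dY <- matrix(rnorm(Cout * Tn * B), Cout, Tn * B)
  ga <- ssvepr:::conv_backward(dY, W, a, C, Tn, B, K)
  gr <- ssvepr:::conv_backward_ref(dY, W, r, C, Tn, B, K)
  expect_equal(ga$dW, gr$dW, tolerance = 1e-12)
  expect_equal(as.numeric(ga$db), as.numeric(gr$db), tolerance = 1e-12)
  expect_equal(ga$dX, gr$dX, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences through the whole network", {
  set.seed(7)
  s <- tiny_spec()
  m <- build_cbam_cnn(s, seed = 11)
  B <- 5
  Xl <- lapply(seq_len(s$n_bands), function(b)
    array(rnorm(s$n_leads * s$window_samples * B), c(s$n_leads, s$window_samples, B)))
  y <- c(1, 2, 3, 1, 2)
  loss_fn <- function(model) {
    fw <- ssvepr:::net_forward(model, Xl, training = TRUE)
    -mean(log(fw$probs[cbind(y, seq_len(B))]))
  }
  fw <- ssvepr:::net_forward(m, Xl, training = TRUE, keep_cache = TRUE)
  gr <- ssvepr:::net_backward(m, fw$cache, y)
  eps <- 1e-6
  for (nm in names(gr)) for (f in names(gr[[nm]])) {
    th <- m$params[[nm]][[f]]
    idx <- sample(length(th), min(length(th), 4))
    for (i in idx) {
      mp <- m; mp$params[[nm]][[f]][i] <- th[i] + eps
      mm <- m; mm$params[[nm]][[f]][i] <- th[i] - eps
      fd <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      an <- gr[[nm]][[f]][i]
      expect_lt(abs(fd - an) / max(1, abs(fd), abs(an)), 1e-5)
    }
  }
})

test_that("training is reproducible to the last bit and records history", {
  s <- tiny_spec()
  st <- fake_stack(n = 12, bands = s$n_bands, leads = s$n_leads,
                   samples = s$window_samples, freqs = c(8, 10, 12))
  cfg <- train_config(epochs = 4, batch_size = 4, val_fraction = 0, seed = 5)
  a <- train_network(build_cbam_cnn(s, seed = 1), st, cfg)
  b <- train_network(build_cbam_cnn(s, seed = 1), st, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
  expect_equal(nrow(a$history), 4L)
  expect_true(all(is.finite(a$history$loss)))
})

test_that("prediction is pure and batching-invariant", {
  s <- tiny_spec()
  st <- fake_stack(n = 12, bands = s$n_bands, leads = s$n_leads,
                   samples = s$window_samples, freqs = c(8, 10, 12))
  m <- train_network(build_cbam_cnn(s, seed = 1), st,
                     train_config(epochs = 2, batch_size = 4, val_fraction = 0, seed = 5))
  full <- predict(m, st)
  expect_lt(max(abs(rowSums(full$probs) - 1)), 1e-6)
  one_by_one <- predict(m, st, chunk = 1L)
  expect_equal(full$probs, one_by_one$probs, tolerance = 1e-12)
  # duplicated trial: identical prediction
  dup <- subset_trials(st, c(3L, 3L))
  pd <- predict(m, dup)
  expect_identical(pd$probs[1, ], pd$probs[2, ])
  expect_equal(sort(unique(full$labels)) %in% c(8, 10, 12), rep(TRUE, length(unique(full$labels))))
})

test_that("geometry violations are reported as shape errors naming the axis", {
  s <- tiny_spec()
  st <- fake_stack(n = 6, bands = s$n_bands + 1, leads = s$n_leads,
                   samples = s$window_samples, freqs = c(8, 10, 12))
  m <- build_cbam_cnn(s, seed = 1)
  err <- expect_error(train_network(m, st), class = "ssvepr_shape_error")
  expect_match(conditionMessage(err), "band")
  st2 <- fake_stack(n = 6, bands = s$n_bands, leads = s$n_leads,
                    samples = s$window_samples + 5, freqs = c(8, 10, 12))
  expect_error(train_network(m, st2), "T_W", class = "ssvepr_shape_error")
})

test_that("kernels larger than the window are construction errors naming the layer", {
  err <- expect_error(model_spec(n_leads = 3, window_samples = 9, conv2_kernel = 15),
                      class = "ssvepr_construction_error")
  expect_match(conditionMessage(err), "conv2")
  expect_error(model_spec(n_leads = 3, window_samples = 100, conv2_kernel = 14),
               class = "ssvepr_validation_error")
  expect_error(model_spec(n_leads = 3, window_samples = 100, rho = 3),
               class = "ssvepr_validation_error")
})

test_that("a non-finite loss aborts with diagnostics instead of training on", {
  s <- tiny_spec()
  st <- fake_stack(n = 9, bands = s$n_bands, leads = s$n_leads,
                   samples = s$window_samples, freqs = c(8, 10, 12), seed = 3)
  st$data[2, 1, 1, 5] <- NaN
  m <- build_cbam_cnn(s, seed = 1)
  expect_error(
    train_network(m, st, train_config(epochs = 2, batch_size = 9,
                                      val_fraction = 0, seed = 2)),
    "learning rate", class = "ssvepr_training_error")
})
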