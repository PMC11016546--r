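# The multi-subband attention network. Four branches, one per filter-bank
# subband: Conv1 (N_L x 1, collapses the lead axis) -> BN -> ELU -> Conv2
# (same-padded temporal kernel) -> BN -> ELU -> Conv3 -> BN -> ELU -> CBAM.
# Branch features are concatenated along the channel axis, refined by a second
# CBAM, passed through Conv4 -> BN -> ELU, flattened, and classified by a
# fully connected softmax head. Forward and backward passes are hand-rolled on
# BLAS matrix products (im2col for the temporal convolutions); all feature
# maps after Conv1 have height 1, so tensors are carried as C x (T*B)
# matrices with the batched CBAM fast path of cbam_batched.R.

#' Network architecture hyperparameters
#'
#' Defaults define a compact net appropriate to the ~144-trial training sets
#' of the 9:1 protocol: 8 filters in each branch convolution, 16 after fusion,
#' a 15-sample (30 ms at 500 Hz) Conv2 kernel, an 11-sample Conv3 kernel, a
#' 3-sample Conv4 kernel, attention reduction ratio 4 and spatial kernel 7.
#'
#' @param n_leads number of leads N_L (Conv1 kernel height).
#' @param window_samples analysis window length T_W in samples (post-decimation).
#' @param n_bands number of filter-bank branches.
#' @param n_classes number of stimulus frequencies.
#' @param k1,k2,k3 filters in Conv1..Conv3 (per branch); `k4` after fusion.
#' @param conv2_kernel,conv3_kernel,conv4_kernel odd temporal kernel lengths.
#' @param rho channel-attention reduction ratio; must divide both `k3` and
#'   `n_bands * k3`.
#' @param z_spatial odd spatial-attention kernel size Z'.
#' @param bn_eps,bn_momentum batch-normalization constants.
#' @return a validated `model_spec` object.
#' @export
model_spec <- function(n_leads, window_samples, n_bands = 4L, n_classes = 4L,
                       k1 = 8L, k2 = 8L, k3 = 8L, k4 = 16L,
                       conv2_kernel = 15L, conv3_kernel = 11L, conv4_kernel = 3L,
                       rho = 4L, z_spatial = 7L,
                       bn_eps = 1e-5, bn_momentum = 0.1) {
  if (n_leads < 1L) abort_valid("n_leads must be >= 1")
  if (n_classes < 2L) abort_valid("n_classes must be >= 2")
  for (nm in c("conv2_kernel", "conv3_kernel", "conv4_kernel", "z_spatial")) {
    v <- get(nm)
    if (v %% 2L == 0L) abort_valid(sprintf("%s must be odd (same padding)", nm))
  }
  for (nm in c("conv2_kernel", "conv3_kernel", "conv4_kernel")) {
    if (get(nm) > window_samples)
      ssvepr_error("construction_error",
                   sprintf("layer %s: kernel length %d exceeds the %d-sample window",
                           sub("_kernel", "", nm), get(nm), window_samples))
  }
  if (k3 %% rho != 0L || (n_bands * k3) %% rho != 0L)
    abort_valid(sprintf("reduction ratio %d must divide k3 = %d and n_bands*k3 = %d",
                        rho, k3, n_bands * k3))
  structure(list(n_leads = as.integer(n_leads),
                 window_samples = as.integer(window_samples),
                 n_bands = as.integer(n_bands), n_classes = as.integer(n_classes),
                 k1 = as.integer(k1), k2 = as.integer(k2), k3 = as.integer(k3),
                 k4 = as.integer(k4),
                 conv2_kernel = as.integer(conv2_kernel),
                 conv3_kernel = as.integer(conv3_kernel),
                 conv4_kernel = as.integer(conv4_kernel),
                 rho = as.integer(rho), z_spatial = as.integer(z_spatial),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "model_spec")
}

conv_init <- function(cout, fan_in) {
  list(W = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in),
       b = rep(0, cout))
}

bn_init <- function(C) list(gamma = rep(1, C), beta = rep(0, C))

#' Build an untrained multi-subband attention network
#'
#' All weights are drawn with seeded variance-scaling (fan-in) initialization;
#' two builds with the same spec and seed are identical. The two attention
#' blocks (per-branch and post-fusion) have independent parameters.
#'
#' @param spec a [model_spec()].
#' @param seed initialization seed.
#' @param cbam whether the two attention blocks are active; `FALSE` yields the
#'   plain-CNN ablation with identical topology and identical non-attention
#'   initial weights for the same seed.
#' @return an `ssvep_cnn` model object.
#' @export
build_cbam_cnn <- function(spec, seed = 1L, cbam = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    pars <- list()
    bn <- list()
    for (b in seq_len(spec$n_bands)) {
      sb <- function(nm) sprintf("%s_b%d", nm, b)
      pars[[sb("conv1")]] <- conv_init(spec$k1, spec$n_leads)
      pars[[sb("bn1")]] <- bn_init(spec$k1)
      pars[[sb("conv2")]] <- conv_init(spec$k2, spec$k1 * spec$conv2_kernel)
      pars[[sb("bn2")]] <- bn_init(spec$k2)
      pars[[sb("conv3")]] <- conv_init(spec$k3, spec$k2 * spec$conv3_kernel)
      pars[[sb("bn3")]] <- bn_init(spec$k3)
      pars[[sb("cbam_ch")]] <- init_channel_params(spec$k3, spec$rho)
      pars[[sb("cbam_sp")]] <- init_spatial_params(spec$z_spatial)
      bn[[sb("bn1")]] <- list(mean = rep(0, spec$k1), var = rep(1, spec$k1))
      bn[[sb("bn2")]] <- list(mean = rep(0, spec$k2), var = rep(1, spec$k2))
      bn[[sb("bn3")]] <- list(mean = rep(0, spec$k3), var = rep(1, spec$k3))
    }
    Cf <- spec$n_bands * spec$k3
    pars[["cbamf_ch"]] <- init_channel_params(Cf, spec$rho)
    pars[["cbamf_sp"]] <- init_spatial_params(spec$z_spatial)
    pars[["conv4"]] <- conv_init(spec$k4, Cf * spec$conv4_kernel)
    pars[["bn4"]] <- bn_init(spec$k4)
    bn[["bn4"]] <- list(mean = rep(0, spec$k4), var = rep(1, spec$k4))
    pars[["fc"]] <- conv_init(spec$n_classes, spec$k4 * spec$window_samples)
    structure(list(spec = spec, params = pars, bn_state = bn,
                   cbam_enabled = isTRUE(cbam), seed = as.integer(seed),
                   class_freqs = NULL, history = NULL, trained = FALSE),
              class = "ssvep_cnn")
  })
}

#' Build the plain-CNN ablation (attention blocks disabled)
#' @inheritParams build_cbam_cnn
#' @return an `ssvep_cnn` with both attention blocks replaced by the identity.
#' @export
build_plain_cnn <- function(spec, seed = 1L) build_cbam_cnn(spec, seed, cbam = FALSE)

active_param_names <- function(model) {
  nms <- names(model$params)
  if (model$cbam_enabled) nms else nms[!grepl("cbam", nms)]
}

#' Number of learnable parameters of a model
#'
#' Counts only active parameters: the plain-CNN ablation excludes the two
#' attention blocks.
#'
#' @param model an `ssvep_cnn`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "ssvep_cnn"))
  sum(vapply(model$params[active_param_names(model)],
             function(p) sum(vapply(p, length, 0L)), 0L))
}

#' @export
print.ssvep_cnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<ssvep_cnn> %s, %d branches, N_L=%d, T_W=%d, %d classes, %d parameters%s\n",
              if (x$cbam_enabled) "with attention" else "plain (no attention)",
              s$n_bands, s$n_leads, s$window_samples, s$n_classes, n_params(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

# ---- layer primitives (batched; tensors carried as C x (T*B) matrices) ----
#
# Same-padded temporal convolutions run through the compiled im2col kernels
# (cpp_conv1d_forward / cpp_conv1d_backward). conv_forward_ref /
# conv_backward_ref are slow pure-R references computed as sums of K shifted
# matrix products; the test suite asserts the two routes agree.

conv_forward <- function(X, W, bvec, C, Tn, B, K) {
  list(Y = cpp_conv1d_forward(X, W, bvec, Tn, B, K), X = X)
}

conv_backward <- function(dY, W, cache, C, Tn, B, K) {
  cpp_conv1d_backward(dY, W, cache$X, Tn, B, K)
}

conv_center_idx <- function(Tn, B, P) {
  as.vector(outer(P + seq_len(Tn), (seq_len(B) - 1L) * (Tn + 2L * P), "+"))
}

conv_forward_ref <- function(X, W, bvec, C, Tn, B, K) {
  P <- (K - 1L) %/% 2L
  Xp <- matrix(0, C, (Tn + 2L * P) * B)
  center <- conv_center_idx(Tn, B, P)
  Xp[, center] <- X
  Y <- matrix(bvec, nrow(W), Tn * B)
  for (k in seq_len(K))
    Y <- Y + W[, (k - 1L) * C + seq_len(C), drop = FALSE] %*%
      Xp[, center + (k - 1L - P), drop = FALSE]
  list(Y = Y, Xp = Xp, center = center)
}

conv_backward_ref <- function(dY, W, cache, C, Tn, B, K) {
  P <- (K - 1L) %/% 2L
  dW <- matrix(0, nrow(W), C * K)
  dXp <- matrix(0, C, ncol(cache$Xp))
  for (k in seq_len(K)) {
    cols <- cache$center + (k - 1L - P)
    blk <- (k - 1L) * C + seq_len(C)
    dW[, blk] <- tcrossprod(dY, cache$Xp[, cols, drop = FALSE])
    dXp[, cols] <- dXp[, cols, drop = FALSE] +
      crossprod(W[, blk, drop = FALSE], dY)
  }
  list(dW = dW, db = rowSums(dY), dX = dXp[, cache$center, drop = FALSE])
}

bn_forward <- function(Y, par, state, eps, momentum, training) {
  if (training) {
    mu <- rowMeans(Y)
    v <- rowMeans(Y * Y) - mu * mu
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- (Y - mu) * inv_std
  list(out = par$gamma * xhat + par$beta, xhat = xhat, inv_std = inv_std,
       state = state)
}

bn_backward <- function(dOut, par, cache) {
  dgamma <- rowSums(dOut * cache$xhat)
  dbeta <- rowSums(dOut)
  dxhat <- dOut * par$gamma
  dx <- cache$inv_std *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- full network forward / backward ----

# stack_arrays: list of per-branch (N_L, T, B) arrays.
net_forward <- function(model, stack_arrays, training = FALSE, keep_cache = FALSE) {
  s <- model$spec
  Tn <- s$window_samples
  B <- dim(stack_arrays[[1]])[3L]
  n <- Tn * B
  cache <- if (keep_cache) list(branches = vector("list", s$n_bands)) else NULL
  branch_out <- vector("list", s$n_bands)
  bn_state <- model$bn_state
  for (b in seq_len(s$n_bands)) {
    sb <- function(nm) sprintf("%s_b%d", nm, b)
    cc <- list()
    X_m <- matrix(stack_arrays[[b]], s$n_leads, n)
    p1 <- model$params[[sb("conv1")]]
    Y1 <- p1$W %*% X_m + p1$b
    f1 <- bn_forward(Y1, model$params[[sb("bn1")]], bn_state[[sb("bn1")]],
                     s$bn_eps, s$bn_momentum, training)
    bn_state[[sb("bn1")]] <- f1$state
    A1 <- cpp_elu(f1$out)
    p2 <- model$params[[sb("conv2")]]
    c2 <- conv_forward(A1, p2$W, p2$b, s$k1, Tn, B, s$conv2_kernel)
    f2 <- bn_forward(c2$Y, model$params[[sb("bn2")]], bn_state[[sb("bn2")]],
                     s$bn_eps, s$bn_momentum, training)
    bn_state[[sb("bn2")]] <- f2$state
    A2 <- cpp_elu(f2$out)
    p3 <- model$params[[sb("conv3")]]
    c3 <- conv_forward(A2, p3$W, p3$b, s$k2, Tn, B, s$conv3_kernel)
    f3 <- bn_forward(c3$Y, model$params[[sb("bn3")]], bn_state[[sb("bn3")]],
                     s$bn_eps, s$bn_momentum, training)
    bn_state[[sb("bn3")]] <- f3$state
    A3 <- cpp_elu(f3$out)
    if (model$cbam_enabled) {
      cb <- cbam_batched_forward(A3, model$params[[sb("cbam_ch")]],
                                 model$params[[sb("cbam_sp")]], s$k3, Tn, B)
      branch_out[[b]] <- cb$out
    } else {
      cb <- NULL
      branch_out[[b]] <- A3
    }
    if (keep_cache) {
      cc$X_m <- X_m; cc$f1 <- f1; cc$A1 <- A1; cc$c2 <- c2
      cc$f2 <- f2; cc$A2 <- A2; cc$c3 <- c3
      cc$f3 <- f3; cc$A3 <- A3; cc$cb <- cb
      cache$branches[[b]] <- cc
    }
  }
  Fm <- do.call(rbind, branch_out)
  Cf <- s$n_bands * s$k3
  if (model$cbam_enabled) {
    cbf <- cbam_batched_forward(Fm, model$params[["cbamf_ch"]],
                                model$params[["cbamf_sp"]], Cf, Tn, B)
    F2 <- cbf$out
  } else {
    cbf <- NULL
    F2 <- Fm
  }
  p4 <- model$params[["conv4"]]
  c4 <- conv_forward(F2, p4$W, p4$b, Cf, Tn, B, s$conv4_kernel)
  f4 <- bn_forward(c4$Y, model$params[["bn4"]], bn_state[["bn4"]],
                   s$bn_eps, s$bn_momentum, training)
  bn_state[["bn4"]] <- f4$state
  A4 <- cpp_elu(f4$out)
  flat <- matrix(A4, s$k4 * Tn, B)
  pf <- model$params[["fc"]]
  logits <- pf$W %*% flat + pf$b
  mx <- apply(logits, 2L, max)
  ex <- exp(sweep(logits, 2L, mx))
  probs <- sweep(ex, 2L, colSums(ex), "/")
  if (keep_cache) {
    cache$cbf <- cbf; cache$c4 <- c4
    cache$f4 <- f4; cache$A4 <- A4; cache$flat <- flat
    cache$probs <- probs; cache$B <- B
  }
  list(probs = probs, logits = logits, cache = cache, bn_state = bn_state)
}

# y: integer class indices (length B). Returns gradients for active params.
net_backward <- function(model, cache, y) {
  s <- model$spec
  Tn <- s$window_samples
  B <- cache$B
  Cf <- s$n_bands * s$k3
  grads <- list()
  dlogits <- cache$probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B
  pf <- model$params[["fc"]]
  grads[["fc"]] <- list(W = tcrossprod(dlogits, cache$flat), b = rowSums(dlogits))
  dflat <- crossprod(pf$W, dlogits)
  dA4 <- matrix(dflat, s$k4, Tn * B)
  dY4bn <- cpp_elu_backward(dA4, cache$f4$out, cache$A4)
  bb4 <- bn_backward(dY4bn, model$params[["bn4"]], cache$f4)
  grads[["bn4"]] <- bb4$grads
  p4 <- model$params[["conv4"]]
  cb4 <- conv_backward(bb4$dx, p4$W, cache$c4, Cf, Tn, B, s$conv4_kernel)
  grads[["conv4"]] <- list(W = cb4$dW, b = cb4$db)
  dF2 <- cb4$dX
  if (model$cbam_enabled) {
    cbb <- cbam_batched_backward(dF2, cache$cbf)
    grads[["cbamf_ch"]] <- cbb$g_ch
    grads[["cbamf_sp"]] <- cbb$g_sp
    dFm <- cbb$dx
  } else dFm <- dF2
  for (b in seq_len(s$n_bands)) {
    sb <- function(nm) sprintf("%s_b%d", nm, b)
    cc <- cache$branches[[b]]
    rows <- (b - 1L) * s$k3 + seq_len(s$k3)
    dOut <- dFm[rows, , drop = FALSE]
    if (model$cbam_enabled) {
      cbb <- cbam_batched_backward(dOut, cc$cb)
      grads[[sb("cbam_ch")]] <- cbb$g_ch
      grads[[sb("cbam_sp")]] <- cbb$g_sp
      dA3 <- cbb$dx
    } else dA3 <- dOut
    dY3bn <- cpp_elu_backward(dA3, cc$f3$out, cc$A3)
    bb3 <- bn_backward(dY3bn, model$params[[sb("bn3")]], cc$f3)
    grads[[sb("bn3")]] <- bb3$grads
    p3 <- model$params[[sb("conv3")]]
    cb3 <- conv_backward(bb3$dx, p3$W, cc$c3, s$k2, Tn, B, s$conv3_kernel)
    grads[[sb("conv3")]] <- list(W = cb3$dW, b = cb3$db)
    dA2 <- cb3$dX
    dY2bn <- cpp_elu_backward(dA2, cc$f2$out, cc$A2)
    bb2 <- bn_backward(dY2bn, model$params[[sb("bn2")]], cc$f2)
    grads[[sb("bn2")]] <- bb2$grads
    p2 <- model$params[[sb("conv2")]]
    cb2 <- conv_backward(bb2$dx, p2$W, cc$c2, s$k1, Tn, B, s$conv2_kernel)
    grads[[sb("conv2")]] <- list(W = cb2$dW, b = cb2$db)
    dA1 <- cb2$dX
    dY1bn <- cpp_elu_backward(dA1, cc$f1$out, cc$A1)
    bb1 <- bn_backward(dY1bn, model$params[[sb("bn1")]], cc$f1)
    grads[[sb("bn1")]] <- bb1$grads
    grads[[sb("conv1")]] <- list(W = tcrossprod(bb1$dx, cc$X_m), b = rowSums(bb1$dx))
  }
  grads
}
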