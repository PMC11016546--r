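# Training (Adam on the cross-entropy loss) and inference for the subband
# attention network.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param epochs maximum number of epochs.
#' @param seed seed fixing initialization-independent training randomness
#'   (batch order, validation split).
#' @param val_fraction fraction of the training trials carved out (stratified)
#'   as a validation set for early stopping; 0 disables early stopping and the
#'   final model is the last-epoch snapshot.
#' @param patience epochs without validation improvement before stopping; the
#'   returned model is the best-validation snapshot.
#' @param beta1,beta2,adam_eps Adam moment constants.
#' @return a `train_config` object.
#' @export
train_config <- function(lr = 1e-3, batch_size = 32L, epochs = 100L, seed = 1L,
                         val_fraction = 0.1, patience = 10L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  if (lr <= 0 || batch_size < 1 || epochs < 1) abort_valid("lr, batch_size and epochs must be positive")
  if (val_fraction < 0 || val_fraction >= 1) abort_valid("val_fraction must be in [0, 1)")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}

# Extract per-branch (N_L, T, B) arrays for the given trial indices.
stack_branch_arrays <- function(stack, idx) {
  d <- dim(stack$data)
  lapply(seq_len(d[2L]), function(b) {
    x <- stack$data[idx, b, , , drop = FALSE]
    dim(x) <- c(length(idx), d[3L], d[4L])
    aperm(x, c(2L, 3L, 1L))
  })
}

check_stack_geometry <- function(model, stack) {
  s <- model$spec
  d <- dim(stack$data)
  if (d[2L] != s$n_bands)
    abort_shape(sprintf("band axis has extent %d, model expects %d bands", d[2L], s$n_bands))
  if (d[3L] != s$n_leads)
    abort_shape(sprintf("lead axis has extent %d, model expects N_L = %d", d[3L], s$n_leads))
  if (d[4L] != s$window_samples)
    abort_shape(sprintf("sample axis has extent %d, model expects T_W = %d", d[4L], s$window_samples))
}

adam_step <- function(params, grads, opt, t, cfg) {
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      opt$m[[nm]][[f]] <- cfg$beta1 * opt$m[[nm]][[f]] + (1 - cfg$beta1) * g
      opt$v[[nm]][[f]] <- cfg$beta2 * opt$v[[nm]][[f]] + (1 - cfg$beta2) * g * g
      mhat <- opt$m[[nm]][[f]] / (1 - cfg$beta1^t)
      vhat <- opt$v[[nm]][[f]] / (1 - cfg$beta2^t)
      params[[nm]][[f]] <- params[[nm]][[f]] - cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps)
    }
  }
  list(params = params, opt = opt)
}

#' Train a network on a labeled subband stack
#'
#' Mini-batch Adam on the cross-entropy loss. Fully deterministic given the
#' model's initialization seed, `cfg$seed` and single-threaded numerics: the
#' same call reproduces the same training curve bit for bit.
#'
#' @param model an untrained [build_cbam_cnn()] / [build_plain_cnn()] model.
#' @param stack a `subband_stack` cropped to the model's window (training
#'   partition).
#' @param cfg a [train_config()].
#' @return the trained `ssvep_cnn`, with `$history` (per-epoch loss, training
#'   accuracy and, when early stopping is active, validation accuracy) and
#'   `$class_freqs` (class-index-to-frequency mapping).
#' @export
train_network <- function(model, stack, cfg = train_config()) {
  stopifnot(inherits(model, "ssvep_cnn"), inherits(stack, "subband_stack"))
  check_stack_geometry(model, stack)
  freqs <- sort(stack$freq_set)
  y_all <- match(stack$labels, freqs)
  if (anyNA(y_all)) abort_valid("labels outside the stack's frequency set")
  if (length(unique(y_all)) < model$spec$n_classes)
    abort_valid("training set must contain at least one trial of every class")
  n <- length(y_all)
  with_seed(cfg$seed, {
    use_val <- cfg$val_fraction > 0
    if (use_val) {
      val_idx <- integer(0)
      for (k in unique(y_all)) {
        cls <- which(y_all == k)
        n_v <- max(1L, round(cfg$val_fraction * length(cls)))
        val_idx <- c(val_idx, sample(cls, n_v))
      }
      val_idx <- sort(val_idx)
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      tr_idx <- seq_len(n); val_idx <- integer(0)
    }
    arr_tr <- stack_branch_arrays(stack, tr_idx)
    y_tr <- y_all[tr_idx]
    arr_val <- if (use_val) stack_branch_arrays(stack, val_idx) else NULL
    y_val <- y_all[val_idx]
    n_tr <- length(y_tr)
    opt <- list(m = lapply(model$params, function(p) lapply(p, function(x) x * 0)),
                v = lapply(model$params, function(p) lapply(p, function(x) x * 0)))
    t_step <- 0L
    best <- list(acc = -Inf, params = NULL, bn = NULL, epoch = 0L)
    wait <- 0L
    hist <- data.frame(epoch = integer(0), loss = numeric(0),
                       train_acc = numeric(0), val_acc = numeric(0))
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; ep_hits <- 0L
      for (start in seq(1L, n_tr, by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, n_tr)]
        Xb <- lapply(arr_tr, function(a) a[, , bi, drop = FALSE])
        yb <- y_tr[bi]
        fw <- net_forward(model, Xb, training = TRUE, keep_cache = TRUE)
        model$bn_state <- fw$bn_state
        pb <- fw$probs[cbind(yb, seq_along(bi))]
        loss <- -mean(log(pmax(pb, 1e-12)))
        if (!is.finite(loss))
          ssvepr_error("training_error",
                       "non-finite training loss: check the input for NaN/Inf; if the input is finite, try a smaller learning rate")
        ep_loss <- ep_loss + loss * length(bi)
        ep_hits <- ep_hits + sum(max.col(t(fw$probs), ties.method = "first") == yb)
        grads <- net_backward(model, fw$cache, yb)
        t_step <- t_step + 1L
        st <- adam_step(model$params, grads, opt, t_step, cfg)
        model$params <- st$params
        opt <- st$opt
      }
      val_acc <- NA_real_
      if (use_val) {
        pv <- net_forward(model, arr_val, training = FALSE)$probs
        val_acc <- mean(max.col(t(pv), ties.method = "first") == y_val)
        if (val_acc > best$acc + 1e-12) {
          best <- list(acc = val_acc, params = model$params,
                       bn = model$bn_state, epoch = ep)
          wait <- 0L
        } else wait <- wait + 1L
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n_tr,
                                     train_acc = ep_hits / n_tr, val_acc = val_acc))
      if (use_val && wait >= cfg$patience) break
    }
    if (use_val && !is.null(best$params)) {
      model$params <- best$params
      model$bn_state <- best$bn
    }
    model$history <- hist
    model$class_freqs <- freqs
    model$trained <- TRUE
    model
  })
}

#' Predict stimulus frequencies for a subband stack
#'
#' Pure function of the trained model and the input: inference uses the
#' stored batch-normalization running statistics, and a duplicated trial
#' receives an identical prediction.
#'
#' @param object a trained `ssvep_cnn`.
#' @param stack a `subband_stack` with geometry matching the model.
#' @param chunk trials per forward pass (memory knob).
#' @param ... unused.
#' @return list with `labels` (predicted frequencies, Hz) and `probs`
#'   (trials x classes matrix; rows sum to 1, columns ordered as
#'   `object$class_freqs`).
#' @export
predict.ssvep_cnn <- function(object, stack, chunk = 64L, ...) {
  stopifnot(inherits(stack, "subband_stack"))
  if (!object$trained) abort_valid("model has not been trained")
  check_stack_geometry(object, stack)
  n <- n_trials(stack)
  probs <- matrix(0, n, object$spec$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    arr <- stack_branch_arrays(stack, idx)
    probs[idx, ] <- t(net_forward(object, arr, training = FALSE)$probs)
  }
  colnames(probs) <- as.character(object$class_freqs)
  labels <- object$class_freqs[max.col(probs, ties.method = "first")]
  list(labels = labels, probs = probs)
}
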