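# Batched attention fast path for height-1 feature maps (the only shape the
# network produces after Conv1). Input is a C x (T*B) matrix, column-major
# over (time, trial). Forward output is numerically identical to applying the
# generic cbam_block() of cbam.R to each trial's C x 1 x T map with the same
# parameters: with height 1, only the centre row of the Z' x Z' spatial kernel
# can overlap data under same padding, so the fast path reads (and writes
# gradients to) that row alone.

cbam_batched_forward <- function(A, p_ch, p_sp, C, Tn, B) {
  pt <- cpp_pool_time(A, Tn, B)
  s_avg <- pt$avg; s_max <- pt$max; j_arg <- pt$arg
  z1a <- p_ch$W1 %*% s_avg + p_ch$b1; h_a <- elu(z1a)
  z1m <- p_ch$W1 %*% s_max + p_ch$b1; h_m <- elu(z1m)
  z <- p_ch$W2 %*% h_a + p_ch$b2 + p_ch$W2 %*% h_m + p_ch$b2
  Lc <- sigmoid(z)                                   # C x B
  A2 <- cpp_scale_bytrial(A, Lc, Tn)
  pc <- cpp_pool_channel(A2)
  p_avg <- matrix(pc$avg, Tn, B)
  p_max <- matrix(pc$max, Tn, B)
  i_arg <- matrix(pc$arg, Tn, B)
  Z <- dim(p_sp$kernel)[1L]
  rc <- (Z + 1L) %/% 2L
  w_a <- p_sp$kernel[rc, , 1L]; w_m <- p_sp$kernel[rc, , 2L]
  P <- (Z - 1L) %/% 2L
  Pa <- matrix(0, Tn + 2L * P, B); Pa[P + seq_len(Tn), ] <- p_avg
  Pm <- matrix(0, Tn + 2L * P, B); Pm[P + seq_len(Tn), ] <- p_max
  q <- matrix(p_sp$bias, Tn, B)
  for (k in seq_len(Z))
    q <- q + w_a[k] * Pa[(k - 1L) + seq_len(Tn), , drop = FALSE] +
             w_m[k] * Pm[(k - 1L) + seq_len(Tn), , drop = FALSE]
  Ls <- sigmoid(q)                                   # Tn x B
  ls_vec <- as.vector(Ls)
  out <- cpp_scale_cols(A2, ls_vec)
  list(out = out, A = A, Lc = Lc, A2 = A2, Ls = Ls, ls_vec = ls_vec,
       s_avg = s_avg, s_max = s_max, j_arg = j_arg,
       z1a = z1a, h_a = h_a, z1m = z1m, h_m = h_m, i_arg = i_arg,
       Pa = Pa, Pm = Pm, p_ch = p_ch, p_sp = p_sp, C = C, Tn = Tn, B = B)
}

cbam_batched_backward <- function(dOut, cc) {
  C <- cc$C; Tn <- cc$Tn; B <- cc$B
  p_ch <- cc$p_ch; p_sp <- cc$p_sp
  Z <- dim(p_sp$kernel)[1L]
  rc <- (Z + 1L) %/% 2L
  P <- (Z - 1L) %/% 2L
  # ---- spatial gate ----
  dA2 <- cpp_scale_cols(dOut, cc$ls_vec)
  dLs <- matrix(cpp_colsums_prod(dOut, cc$A2), Tn, B)
  dq <- dLs * cc$Ls * (1 - cc$Ls)
  dbias <- sum(dq)
  dw_a <- numeric(Z); dw_m <- numeric(Z)
  dPa <- matrix(0, Tn + 2L * P, B); dPm <- matrix(0, Tn + 2L * P, B)
  w_a <- p_sp$kernel[rc, , 1L]; w_m <- p_sp$kernel[rc, , 2L]
  for (k in seq_len(Z)) {
    rows <- (k - 1L) + seq_len(Tn)
    dw_a[k] <- sum(cc$Pa[rows, , drop = FALSE] * dq)
    dw_m[k] <- sum(cc$Pm[rows, , drop = FALSE] * dq)
    dPa[rows, ] <- dPa[rows, ] + w_a[k] * dq
    dPm[rows, ] <- dPm[rows, ] + w_m[k] * dq
  }
  dp_avg <- dPa[P + seq_len(Tn), , drop = FALSE]
  dp_max <- dPm[P + seq_len(Tn), , drop = FALSE]
  dA2 <- cpp_add_to_cols(dA2, as.vector(dp_avg) / C)
  j_all <- seq_len(Tn * B)
  lin <- (j_all - 1L) * C + as.vector(cc$i_arg)
  dA2[lin] <- dA2[lin] + as.vector(dp_max)
  dK <- array(0, dim(p_sp$kernel))
  dK[rc, , 1L] <- dw_a; dK[rc, , 2L] <- dw_m
  # ---- channel gate ----
  dA <- cpp_scale_bytrial(dA2, cc$Lc, Tn)
  dLc <- cpp_pool_time(dA2 * cc$A, Tn, B)$avg * Tn
  dz <- dLc * cc$Lc * (1 - cc$Lc)
  dW2 <- tcrossprod(dz, cc$h_a) + tcrossprod(dz, cc$h_m)
  db2 <- 2 * rowSums(dz)
  dzW2 <- crossprod(p_ch$W2, dz)
  dh_a <- dzW2 * elu_grad(cc$z1a, cc$h_a)
  dh_m <- dzW2 * elu_grad(cc$z1m, cc$h_m)
  dW1 <- tcrossprod(dh_a, cc$s_avg) + tcrossprod(dh_m, cc$s_max)
  db1 <- rowSums(dh_a) + rowSums(dh_m)
  ds_avg <- crossprod(p_ch$W1, dh_a)
  ds_max <- crossprod(p_ch$W1, dh_m)
  dA <- cpp_add_bytrial(dA, ds_avg / Tn, Tn)
  c_all <- rep(seq_len(C), B)
  b_all <- rep(seq_len(B), each = C)
  j_col <- (b_all - 1L) * Tn + as.vector(cc$j_arg)
  lin2 <- (j_col - 1L) * C + c_all
  dA[lin2] <- dA[lin2] + as.vector(ds_max)
  list(dx = dA,
       g_ch = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       g_sp = list(kernel = dK, bias = dbias))
}
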