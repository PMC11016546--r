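# Convolutional block attention: channel attention (shared two-layer
# perceptron over global average- and max-pooled channel descriptors, summed,
# sigmoid) followed by spatial attention (channel-wise average/max pooling to
# two planes, Z' x Z' convolution, sigmoid). Pure array operations on a
# feature map N of shape C x H x W; the network applies the same parameters
# through a batched fast path for H = 1 maps.

check_feature_map <- function(N) {
  if (length(dim(N)) != 3L)
    abort_shape("feature map must be a 3-axis array (channels x height x width)")
  if (any(dim(N) < 1L)) abort_shape("feature map axes must have positive extent")
  if (!all(is.finite(N))) abort_valid("feature map contains non-finite values")
  invisible(N)
}

#' Channel-attention parameters
#'
#' The shared perceptron `C -> C/rho -> C` applied to both pooled descriptors.
#'
#' @param W1 hidden weight matrix, `(C/rho) x C`.
#' @param b1 hidden bias, length `C/rho`.
#' @param W2 output weight matrix, `C x (C/rho)`.
#' @param b2 output bias, length `C`.
#' @return a `channel_attention_params` object.
#' @export
channel_attention_params <- function(W1, b1, W2, b2) {
  if (ncol(W2) != nrow(W1) || nrow(W2) != ncol(W1))
    abort_shape("perceptron weight shapes inconsistent: need (C/rho x C) and (C x C/rho)")
  structure(list(W1 = W1, b1 = as.numeric(b1), W2 = W2, b2 = as.numeric(b2)),
            class = "channel_attention_params")
}

#' Spatial-attention parameters
#'
#' One 2-input-plane convolution kernel of odd size `Z' x Z'` plus a bias.
#'
#' @param kernel numeric array `Z' x Z' x 2` (the two input planes are the
#'   channel-wise average and maximum).
#' @param bias scalar bias.
#' @return a `spatial_attention_params` object.
#' @export
spatial_attention_params <- function(kernel, bias = 0) {
  d <- dim(kernel)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 2L)
    abort_shape("spatial kernel must be a Z' x Z' x 2 array")
  if (d[1] %% 2L == 0L)
    abort_valid("spatial kernel size Z' must be odd (same-padding symmetry)")
  structure(list(kernel = kernel, bias = as.numeric(bias)),
            class = "spatial_attention_params")
}

#' Channel attention map
#'
#' `L_c = sigmoid(MLP(AvgPool(N)) + MLP(MaxPool(N)))`, where both pools reduce
#' each channel's H x W plane to a scalar and the perceptron (hidden ELU) is
#' shared between the two pooling paths.
#'
#' @param N feature map, C x H x W.
#' @param p [channel_attention_params()] sized for C channels.
#' @return the channel attention map as a C x 1 x 1 array with entries in (0, 1).
#' @export
channel_attention <- function(N, p) {
  check_feature_map(N)
  C <- dim(N)[1L]
  if (ncol(p$W1) != C)
    abort_shape(sprintf("channel-attention perceptron expects %d channels, feature map has %d",
                        ncol(p$W1), C))
  s_avg <- apply(N, 1L, mean)
  s_max <- apply(N, 1L, max)
  mlp <- function(s) as.numeric(p$W2 %*% elu(p$W1 %*% s + p$b1) + p$b2)
  array(sigmoid(mlp(s_avg) + mlp(s_max)), dim = c(C, 1L, 1L))
}

#' Apply a channel attention map
#'
#' `N'[c,h,w] = L_c[c] * N[c,h,w]` (element-wise multiplication with the
#' channel gate broadcast over the spatial axes).
#'
#' @param L_c C x 1 x 1 attention map (or length-C vector).
#' @param N feature map, C x H x W.
#' @return the refined feature map N'.
#' @export
apply_channel <- function(L_c, N) {
  check_feature_map(N)
  g <- as.numeric(L_c)
  if (length(g) != dim(N)[1L])
    abort_shape("channel attention map length does not match the channel axis")
  N * array(g, dim = dim(N))  # channel axis is fastest-varying: plain recycling
}

#' Spatial attention map
#'
#' Pools N' across the channel axis into average and maximum H x W planes,
#' stacks them, convolves with the `Z' x Z'` kernel under same padding, and
#' applies the sigmoid: `L_s = sigmoid(f_Z'([AvgPool(N'); MaxPool(N')]))`.
#'
#' @param N_prime feature map, C x H x W.
#' @param p [spatial_attention_params()].
#' @return the spatial attention map as a 1 x H x W array with entries in (0, 1).
#' @export
spatial_attention <- function(N_prime, p) {
  check_feature_map(N_prime)
  d <- dim(N_prime)
  H <- d[2L]; W <- d[3L]
  p_avg <- apply(N_prime, c(2L, 3L), mean)
  p_max <- apply(N_prime, c(2L, 3L), max)
  if (H == 1L) { p_avg <- matrix(p_avg, 1L, W); p_max <- matrix(p_max, 1L, W) }
  Z <- dim(p$kernel)[1L]
  pc <- (Z - 1L) %/% 2L
  pad <- function(m) {
    out <- matrix(0, H + 2L * pc, W + 2L * pc)
    out[pc + seq_len(H), pc + seq_len(W)] <- m
    out
  }
  Pa <- pad(p_avg); Pm <- pad(p_max)
  q <- matrix(p$bias, H, W)
  for (i in seq_len(Z)) for (j in seq_len(Z)) {
    q <- q + p$kernel[i, j, 1L] * Pa[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)] +
             p$kernel[i, j, 2L] * Pm[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)]
  }
  array(sigmoid(q), dim = c(1L, H, W))
}

#' Apply a spatial attention map
#'
#' `N''[c,h,w] = L_s[h,w] * N'[c,h,w]` (the location gate broadcast over
#' channels).
#'
#' @param L_s 1 x H x W attention map (or H x W matrix).
#' @param N_prime feature map, C x H x W.
#' @return the refined feature map N''.
#' @export
apply_spatial <- function(L_s, N_prime) {
  check_feature_map(N_prime)
  d <- dim(N_prime)
  g <- array(L_s, dim = c(d[2L], d[3L]))
  if (length(L_s) != d[2L] * d[3L])
    abort_shape("spatial attention map extent does not match H x W")
  out <- N_prime
  for (c_i in seq_len(d[1L])) out[c_i, , ] <- N_prime[c_i, , ] * g
  out
}

#' Full convolutional block attention
#'
#' Channel attention strictly first, then spatial attention:
#' `N'' = apply_spatial(spatial_attention(N'), N')` with
#' `N' = apply_channel(channel_attention(N), N)`. Both gates lie in (0, 1),
#' so the block is contractive in magnitude element-wise.
#'
#' @param N feature map, C x H x W.
#' @param p_c [channel_attention_params()].
#' @param p_s [spatial_attention_params()].
#' @return the refined feature map N''.
#' @export
cbam_block <- function(N, p_c, p_s) {
  N_prime <- apply_channel(channel_attention(N, p_c), N)
  apply_spatial(spatial_attention(N_prime, p_s), N_prime)
}

# Seeded initializers (variance-scaling fan-in), used by the network builder.
init_channel_params <- function(C, rho) {
  if (C %% rho != 0L)
    abort_valid(sprintf("reduction ratio %d must divide the channel count %d", rho, C))
  Ch <- C %/% rho
  channel_attention_params(
    W1 = matrix(stats::rnorm(Ch * C, sd = sqrt(2 / C)), Ch, C), b1 = rep(0, Ch),
    W2 = matrix(stats::rnorm(C * Ch, sd = sqrt(2 / Ch)), C, Ch), b2 = rep(0, C))
}

init_spatial_params <- function(Z) {
  spatial_attention_params(
    kernel = array(stats::rnorm(Z * Z * 2, sd = sqrt(2 / (Z * Z * 2))), c(Z, Z, 2L)),
    bias = 0)
}
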