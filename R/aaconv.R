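# Attention-augmented convolution (AAConv): a 1-D convolution branch run in
# parallel with multi-head self-attention over the same positions; the two
# outputs are concatenated along the channel axis and passed through ReLU.
# Convolution uses 'same' padding so both branches agree on position count.

#' AAConv layer configuration
#'
#' @param out_channels Total output channels of the layer (conv branch +
#'   attention branch), default 100.
#' @param kernel_size Convolution kernel width, default 10.
#' @param num_heads Number of self-attention heads, default 1.
#' @param attn_channels Channels produced by the attention branch (the conv
#'   branch gets the remainder).  Default 20: attention augments rather than
#'   replaces convolution, so it takes the minority share.
#' @param d_kh Key depth per head; default \code{attn_channels / num_heads}.
#' @return List of class \code{aaconv_config}.
#' @export
aaconv_config <- function(out_channels = 100L, kernel_size = 10L,
                          num_heads = 1L, attn_channels = 20L,
                          d_kh = NULL) {
  if (attn_channels >= out_channels)
    stop("attention channels must leave room for the convolution branch")
  if (attn_channels %% num_heads != 0L)
    stop("attn_channels must be divisible by num_heads")
  if (is.null(d_kh)) d_kh <- attn_channels %/% num_heads
  if (d_kh < 1L || num_heads < 1L) stop("d_kh and num_heads must be >= 1")
  structure(list(out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 num_heads = as.integer(num_heads),
                 attn_channels = as.integer(attn_channels),
                 conv_channels = as.integer(out_channels - attn_channels),
                 d_kh = as.integer(d_kh)),
            class = "aaconv_config")
}

#' Initialise AAConv weights
#'
#' @param in_channels Input channel count (21 for one-hot peptides).
#' @param config An [aaconv_config()].
#' @return Nested list of parameter arrays: \code{conv} (W, b) and
#'   \code{attn} (Wq, Wk, Wv, Wo, bo); heads occupy contiguous column blocks.
#' @export
aaconv_init <- function(in_channels, config = aaconv_config()) {
  nh <- config$num_heads
  dk <- config$d_kh * nh          # stacked key/query width
  dv <- config$attn_channels      # stacked value width
  list(conv = conv1d_init(in_channels, config$conv_channels,
                          config$kernel_size),
       attn = list(Wq = init_mat(in_channels, dk, gain = 1),
                   Wk = init_mat(in_channels, dk, gain = 1),
                   Wv = init_mat(in_channels, dv, gain = 1),
                   Wo = init_mat(dv, config$attn_channels, gain = 1),
                   bo = numeric(config$attn_channels)))
}

## ---- batched internals -----------------------------------------------------

mhsa_forward_batch <- function(x, w, config) {
  d <- dim(x); B <- d[1]; L <- d[2]
  nh <- config$num_heads
  dkh <- config$d_kh
  dvh <- config$attn_channels %/% nh
  xf <- flatten23(x)
  Q <- xf %*% w$Wq
  K <- xf %*% w$Wk
  V <- xf %*% w$Wv
  H <- matrix(0, B * L, config$attn_channels)
  A_list <- vector("list", B * nh)
  for (b in seq_len(B)) {
    rows <- seq(b, by = B, length.out = L)  # column-major flatten layout
    for (h in seq_len(nh)) {
      qc <- ((h - 1L) * dkh + 1L):(h * dkh)
      vc <- ((h - 1L) * dvh + 1L):(h * dvh)
      S <- tcrossprod(Q[rows, qc, drop = FALSE],
                      K[rows, qc, drop = FALSE]) / sqrt(dkh)
      A <- softmax_rows(S)
      A_list[[(b - 1L) * nh + h]] <- A
      H[rows, vc] <- A %*% V[rows, vc, drop = FALSE]
    }
  }
  out <- sweep(H %*% w$Wo, 2, w$bo, `+`)
  dim(out) <- c(B, L, config$attn_channels)
  list(out = out,
       cache = list(xf = xf, Q = Q, K = K, V = V, H = H, A = A_list,
                    B = B, L = L))
}

mhsa_backward_batch <- function(dy, w, config, cache) {
  B <- cache$B; L <- cache$L
  nh <- config$num_heads
  dkh <- config$d_kh
  dvh <- config$attn_channels %/% nh
  dyf <- dy; dim(dyf) <- c(B * L, config$attn_channels)
  dWo <- crossprod(cache$H, dyf)
  dbo <- colSums(dyf)
  dH <- dyf %*% t(w$Wo)
  dQ <- matrix(0, B * L, ncol(w$Wq))
  dK <- matrix(0, B * L, ncol(w$Wk))
  dV <- matrix(0, B * L, ncol(w$Wv))
  for (b in seq_len(B)) {
    rows <- seq(b, by = B, length.out = L)
    for (h in seq_len(nh)) {
      qc <- ((h - 1L) * dkh + 1L):(h * dkh)
      vc <- ((h - 1L) * dvh + 1L):(h * dvh)
      A <- cache$A[[(b - 1L) * nh + h]]
      dOh <- dH[rows, vc, drop = FALSE]
      dV[rows, vc] <- crossprod(A, dOh)
      dA <- tcrossprod(dOh, cache$V[rows, vc, drop = FALSE])
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, qc] <- dS %*% cache$K[rows, qc, drop = FALSE] / sqrt(dkh)
      dK[rows, qc] <- crossprod(dS, cache$Q[rows, qc, drop = FALSE]) /
        sqrt(dkh)
    }
  }
  dxf <- dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  list(dx = unflatten23(dxf, B, L),
       grads = list(Wq = crossprod(cache$xf, dQ),
                    Wk = crossprod(cache$xf, dK),
                    Wv = crossprod(cache$xf, dV),
                    Wo = dWo, bo = dbo))
}

aaconv_forward_batch <- function(x, par, config) {
  cv <- conv1d_forward(x, par$conv, padding = "same")
  at <- mhsa_forward_batch(x, par$attn, config)
  if (dim(cv$out)[2] != dim(at$out)[2])
    stop("AAConv branch position counts differ: conv ", dim(cv$out)[2],
         " vs attention ", dim(at$out)[2])
  d <- dim(cv$out)
  pre <- array(0, dim = c(d[1], d[2], config$out_channels))
  pre[, , seq_len(config$conv_channels)] <- cv$out
  pre[, , config$conv_channels + seq_len(config$attn_channels)] <- at$out
  rl <- relu_forward(pre)
  list(out = rl$out,
       cache = list(conv = cv$cache, attn = at$cache, relu = rl$cache))
}

aaconv_backward_batch <- function(dy, par, config, cache) {
  dpre <- relu_backward(dy, cache$relu)
  dconv <- dpre[, , seq_len(config$conv_channels), drop = FALSE]
  dattn <- dpre[, , config$conv_channels + seq_len(config$attn_channels),
                drop = FALSE]
  bc <- conv1d_backward(dconv, par$conv, cache$conv)
  ba <- mhsa_backward_batch(dattn, par$attn, config, cache$attn)
  list(dx = bc$dx + ba$dx,
       grads = list(conv = bc$grads, attn = ba$grads))
}

## ---- single-matrix public surface -----------------------------------------

#' Convolution branch of AAConv
#'
#' 1-D convolution over positions with 'same' zero padding, so the output
#' keeps the input's position count.
#'
#' @param X Feature matrix, positions x channels.
#' @param weights Conv parameters (\code{W}: kernel x in x out, \code{b}).
#' @param padding \code{"same"} (default) or \code{"valid"}.
#' @return Feature matrix, positions x conv channels.
#' @export
conv_branch <- function(X, weights, padding = "same") {
  x <- array(X, dim = c(1L, nrow(X), ncol(X)))
  out <- conv1d_forward(x, weights, padding = padding)$out
  matrix(out, dim(out)[2], dim(out)[3])
}

#' Multi-head scaled dot-product self-attention
#'
#' Per head h: \eqn{O_h = softmax(Q K^T / \sqrt{d_{kh}}) V} with
#' \eqn{Q = X W_q}, \eqn{K = X W_k}, \eqn{V = X W_v}; head outputs are
#' concatenated and projected by \eqn{W^O}.  No positional encoding is
#' added, so the map is equivariant under position permutations.
#'
#' @param X Feature matrix, positions x channels.
#' @param weights List with Wq, Wk, Wv, Wo, bo (heads in column blocks).
#' @param config An [aaconv_config()].
#' @return Feature matrix, positions x attention channels.
#' @export
multi_head_self_attention <- function(X, weights, config = aaconv_config()) {
  if (any(!is.finite(X))) stop("non-finite values in attention input")
  x <- array(X, dim = c(1L, nrow(X), ncol(X)))
  out <- mhsa_forward_batch(x, weights, config)$out
  matrix(out, dim(out)[2], dim(out)[3])
}

#' AAConv forward pass
#'
#' \code{ReLU(Concat[Conv(X), MHA(X)])}: channel-wise concatenation of the
#' convolution branch and the self-attention branch, then ReLU.
#'
#' @param X Feature matrix, positions x channels (e.g. 50 x 21 one-hot).
#' @param weights Output of [aaconv_init()].
#' @param config An [aaconv_config()].
#' @return Feature matrix, positions x \code{out_channels}; entries >= 0.
#' @export
aaconv_forward <- function(X, weights, config = aaconv_config()) {
  x <- array(X, dim = c(1L, nrow(X), ncol(X)))
  out <- aaconv_forward_batch(x, weights, config)$out
  matrix(out, dim(out)[2], dim(out)[3])
}
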