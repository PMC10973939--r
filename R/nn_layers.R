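# Low-level neural-network building blocks: forward passes with caches and
# matching hand-derived backward passes.  Batched inputs use the layout
# (batch, positions, channels) for sequence tensors and (batch, features)
# for flat tensors; R's column-major arrays let dims 1:2 collapse to a
# (batch*positions, channels) matrix without copying semantics getting in
# the way.  All gradients are checked against central finite differences in
# the test suite.

# He-style initialisation; draws come from the current RNG stream so that
# build_model() under a seed is fully deterministic.
init_mat <- function(nin, nout, gain = sqrt(2)) {
  matrix(rnorm(nin * nout, sd = gain / sqrt(nin)), nin, nout)
}

flatten23 <- function(x) {
  # (B, L, C) -> (B*L, C)
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

unflatten23 <- function(x, B, L) {
  dim(x) <- c(B, L, ncol(x))
  x
}

## ---- 1-D convolution over positions --------------------------------------

conv1d_init <- function(in_ch, out_ch, k) {
  list(W = array(rnorm(k * in_ch * out_ch, sd = sqrt(2 / (k * in_ch))),
                 dim = c(k, in_ch, out_ch)),
       b = numeric(out_ch))
}

# padding: "valid" (no padding, L_out = L - k + 1) or "same" (zero pad so
# L_out = L; left pad floor((k-1)/2), remainder right).
conv1d_forward <- function(x, par, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  k <- dim(par$W)[1]
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  if (C != dim(par$W)[2])
    stop("conv1d: input has ", C, " channels but weights expect ",
         dim(par$W)[2])
  if (padding == "same") {
    pl <- (k - 1L) %/% 2L; pr <- k - 1L - pl
    xp <- array(0, dim = c(B, L + k - 1L, C))
    xp[, pl + seq_len(L), ] <- x
  } else {
    pl <- 0L
    xp <- x
  }
  Lp <- dim(xp)[2]
  Lout <- Lp - k + 1L
  if (Lout < 1L) stop("conv1d: kernel size ", k, " exceeds input length ", L)
  Cout <- dim(par$W)[3]
  y <- matrix(rep(par$b, each = B * Lout), B * Lout, Cout)
  for (t in seq_len(k)) {
    xt <- xp[, t:(t + Lout - 1L), , drop = FALSE]
    dim(xt) <- c(B * Lout, C)
    y <- y + xt %*% par$W[t, , ]
  }
  dim(y) <- c(B, Lout, Cout)
  list(out = y, cache = list(xp = xp, pl = pl, L = L, padding = padding))
}

conv1d_backward <- function(dy, par, cache) {
  k <- dim(par$W)[1]; C <- dim(par$W)[2]; Cout <- dim(par$W)[3]
  xp <- cache$xp
  B <- dim(xp)[1]; Lp <- dim(xp)[2]
  Lout <- dim(dy)[2]
  dyf <- dy; dim(dyf) <- c(B * Lout, Cout)
  dW <- array(0, dim = dim(par$W))
  dxp <- array(0, dim = dim(xp))
  for (t in seq_len(k)) {
    idx <- t:(t + Lout - 1L)
    xt <- xp[, idx, , drop = FALSE]
    dim(xt) <- c(B * Lout, C)
    dW[t, , ] <- crossprod(xt, dyf)
    dxt <- dyf %*% t(matrix(par$W[t, , ], C, Cout))
    dim(dxt) <- c(B, Lout, C)
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + dxt
  }
  dx <- dxp[, cache$pl + seq_len(cache$L), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = colSums(dyf)))
}

## ---- max pooling (size 2, stride 2) --------------------------------------

maxpool2_forward <- function(x) {
  d <- dim(x); Lout <- d[2] %/% 2L
  a <- x[, seq(1L, 2L * Lout, by = 2L), , drop = FALSE]
  b <- x[, seq(2L, 2L * Lout, by = 2L), , drop = FALSE]
  takea <- a >= b
  list(out = pmax(a, b),
       cache = list(takea = takea, L = d[2], Lout = Lout))
}

maxpool2_backward <- function(dy, cache) {
  d <- dim(dy); B <- d[1]; C <- d[3]
  dx <- array(0, dim = c(B, cache$L, C))
  dx[, seq(1L, 2L * cache$Lout, by = 2L), ] <- dy * cache$takea
  dx[, seq(2L, 2L * cache$Lout, by = 2L), ] <- dy * !cache$takea
  dx
}

## ---- batch normalisation --------------------------------------------------

# Normalises each channel over all batch rows (and positions, for sequence
# tensors flattened to (B*L, C) before the call).  eps and momentum follow
# the common defaults.
batchnorm_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

batchnorm_forward <- function(x, par, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    par$run_mean <- (1 - momentum) * par$run_mean + momentum * mu
    par$run_var <- (1 - momentum) * par$run_var + momentum * v
  } else {
    mu <- par$run_mean
    v <- par$run_var
    xc <- sweep(x, 2, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, par$gamma, `*`), 2, par$beta, `+`)
  list(out = y, par = par,
       cache = list(xhat = xhat, istd = istd, training = training))
}

batchnorm_backward <- function(dy, par, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, par$gamma, `*`)
  if (cache$training) {
    dx <- sweep(sweep(dxhat, 2, colMeans(dxhat)) -
                  sweep(xhat, 2, colMeans(dxhat * xhat), `*`),
                2, cache$istd, `*`)
  } else {
    dx <- sweep(dxhat, 2, cache$istd, `*`)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- dropout / relu / linear ----------------------------------------------

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0)
    return(list(out = x, cache = NULL))
  keep <- (runif(length(x)) >= rate) / (1 - rate)
  dim(keep) <- dim(x)
  list(out = x * keep, cache = keep)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

linear_init <- function(nin, nout, gain = sqrt(2)) {
  list(W = init_mat(nin, nout, gain), b = numeric(nout))
}

linear_forward <- function(x, par) {
  list(out = sweep(x %*% par$W, 2, par$b, `+`), cache = x)
}

linear_backward <- function(dy, par, cache) {
  list(dx = dy %*% t(par$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))
}

## ---- softmax + cross-entropy ----------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class index per row (1-based).  Returns mean loss and the
# gradient of the mean loss w.r.t. the logits.
softmax_xent <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

## ---- parameter-tree utilities + Adam --------------------------------------

# Parameters live in nested lists whose leaves are numeric arrays; these
# helpers walk two trees of identical shape.
tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) tree_map(f, el)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
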