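# Linear-complexity multi-head flow-attention.  Queries and keys are mapped
# through a sigmoid into (0,1); per-token incoming flow I (at sinks/queries)
# and outgoing flow O (at sources/keys) are the row and column sums of the
# nonnegative interaction mass phi(Q) phi(K)^T.  Conservation — each token
# exchanges exactly one unit of flow with the external network — is imposed
# by dividing by I and O.  "Competition" reweights values by a softmax over
# the conserved source outflow O'; "allocation" gates the aggregated result
# by a sigmoid of the conserved sink inflow I'.  Evaluating right-to-left
# never materialises the n x m interaction matrix, giving O(n) cost; the
# dense oracle below materialises it for verification.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Flow-attention configuration
#'
#' @param hid_dim Hidden (projection) dimension, default 44.
#' @param num_heads Number of heads, default 4; must divide \code{hid_dim}.
#' @param dropout Dropout ratio applied to the output during training,
#'   default 0.05.
#' @return List of class \code{flow_attention_config}.
#' @export
flow_attention_config <- function(hid_dim = 44L, num_heads = 4L,
                                  dropout = 0.05) {
  if (hid_dim %% num_heads != 0L)
    stop("hid_dim (", hid_dim, ") must be divisible by num_heads (",
         num_heads, ")")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(hid_dim = as.integer(hid_dim),
                 num_heads = as.integer(num_heads),
                 dropout = dropout),
            class = "flow_attention_config")
}

#' Initialise flow-attention weights
#'
#' @param d_in Input feature dimension.
#' @param config A [flow_attention_config()].
#' @return List with projection matrices Wq, Wk, Wv (d_in x hid_dim), the
#'   output transform Wo (hid_dim x hid_dim) and bias bo.  Heads occupy
#'   contiguous column blocks of the projections.
#' @export
flow_attention_init <- function(d_in, config = flow_attention_config()) {
  h <- config$hid_dim
  list(Wq = init_mat(d_in, h, gain = 1),
       Wk = init_mat(d_in, h, gain = 1),
       Wv = init_mat(d_in, h, gain = 1),
       Wo = init_mat(h, h, gain = 1),
       bo = numeric(h))
}

#' Sigmoid map to the open unit interval
#'
#' Elementwise \eqn{1 / (1 + e^{-x})}; maps queries and keys to the
#' non-negative region so all flows are strictly positive.
#'
#' @param M Numeric matrix (finite entries).
#' @return Matrix of the same shape with entries strictly in (0, 1).
#' @export
nonneg_map <- function(M) {
  if (any(!is.finite(M))) stop("non-finite values in nonneg_map input")
  sigmoid(M)
}

#' Incoming flow at each sink
#'
#' \eqn{I_i = \phi(Q_i) \cdot \sum_j \phi(K_j)}: the total interaction mass
#' each query receives from all keys.  Strictly positive for sigmoid maps.
#'
#' @param phiQ n x d matrix of mapped queries.
#' @param phiK m x d matrix of mapped keys.
#' @return Positive vector of length n.
#' @export
incoming_flow <- function(phiQ, phiK) {
  if (ncol(phiQ) != ncol(phiK))
    stop("feature dimensions differ: ", ncol(phiQ), " vs ", ncol(phiK))
  drop(phiQ %*% colSums(phiK))
}

#' Outgoing flow at each source
#'
#' \eqn{O_j = \phi(K_j) \cdot \sum_i \phi(Q_i)}: the total interaction mass
#' each key emits towards all queries.
#'
#' @inheritParams incoming_flow
#' @return Positive vector of length m.
#' @export
outgoing_flow <- function(phiQ, phiK) {
  if (ncol(phiQ) != ncol(phiK))
    stop("feature dimensions differ: ", ncol(phiQ), " vs ", ncol(phiK))
  drop(phiK %*% colSums(phiQ))
}

#' Source-side competition
#'
#' With sink inflows fixed at one unit (queries normalised by I), the
#' conserved outflow of source j is \eqn{O'_j = \phi(K_j) \cdot \sum_i
#' \phi(Q_i)/I_i}.  Sources then compete: values are reweighted by
#' \code{softmax(O')} over sources.
#'
#' @param phiQ,phiK Mapped query/key matrices.
#' @param V m x dv value matrix.
#' @param I Incoming-flow vector (strictly positive).
#' @return List with \code{O_prime} (length m), \code{weights}
#'   (softmax(O'), sums to 1) and \code{V_prime} (reweighted values).
#' @export
competition <- function(phiQ, phiK, V, I) {
  if (any(I <= 0)) stop("conservation violation: non-positive incoming flow")
  O_prime <- drop(phiK %*% colSums(phiQ / I))
  w <- exp(O_prime - max(O_prime))
  w <- w / sum(w)
  list(O_prime = O_prime, weights = w, V_prime = V * w)
}

#' Sink-side allocation
#'
#' With source outflows fixed at one unit (keys normalised by O), the
#' conserved inflow of sink i is \eqn{I'_i = \phi(Q_i) \cdot \sum_j
#' \phi(K_j)/O_j}.  The attention output is
#' \eqn{R = Sigmoid(I') \odot [(\phi(Q)/I)(\phi(K)^T V')]}, evaluated
#' right-to-left so no n x m matrix is formed.
#'
#' @param phiQ,phiK Mapped query/key matrices.
#' @param V_prime Competed values from [competition()].
#' @param O Outgoing-flow vector (strictly positive).
#' @param I Incoming-flow vector (strictly positive).
#' @return n x dv matrix R of attention outputs.
#' @export
allocation <- function(phiQ, phiK, V_prime, O, I) {
  if (any(O <= 0)) stop("conservation violation: non-positive outgoing flow")
  if (any(I <= 0)) stop("conservation violation: non-positive incoming flow")
  I_prime <- drop(phiQ %*% colSums(phiK / O))
  sigmoid(I_prime) * ((phiQ / I) %*% crossprod(phiK, V_prime))
}

#' Flow-attention forward pass (linear form)
#'
#' Full multi-head flow-attention for one sequence: linear projections,
#' sigmoid maps, flows, competition, allocation per head; heads are
#' concatenated and passed through the output transform.  Cost is linear in
#' the number of positions for fixed dimensions.
#'
#' @param X n x d_in feature matrix (positions as tokens).
#' @param weights Output of [flow_attention_init()].
#' @param config A [flow_attention_config()].
#' @param count_ops If TRUE, attach the multiply-add count as attribute
#'   \code{"ops"} on the result.
#' @return n x hid_dim output matrix R'.
#' @export
flow_attention_forward <- function(X, weights, config = flow_attention_config(),
                                   count_ops = FALSE) {
  if (any(!is.finite(X))) stop("non-finite values in flow-attention input")
  n <- nrow(X); d_in <- ncol(X)
  h <- config$hid_dim; nh <- config$num_heads
  dh <- h %/% nh
  ops <- 0
  Q <- X %*% weights$Wq; K <- X %*% weights$Wk; V <- X %*% weights$Wv
  ops <- ops + 3 * n * d_in * h
  R <- matrix(0, n, h)
  for (head in seq_len(nh)) {
    cols <- ((head - 1L) * dh + 1L):(head * dh)
    phiQ <- sigmoid(Q[, cols, drop = FALSE])
    phiK <- sigmoid(K[, cols, drop = FALSE])
    Vh <- V[, cols, drop = FALSE]
    ops <- ops + 2 * n * dh
    I <- incoming_flow(phiQ, phiK)
    O <- outgoing_flow(phiQ, phiK)
    ops <- ops + 4 * n * dh
    cmp <- competition(phiQ, phiK, Vh, I)
    ops <- ops + 3 * n * dh + 3 * n
    R[, cols] <- allocation(phiQ, phiK, cmp$V_prime, O, I)
    ops <- ops + 4 * n * dh + 2 * dh * dh + n * dh * dh
  }
  out <- sweep(R %*% weights$Wo, 2, weights$bo, `+`)
  ops <- ops + n * h * h + n * h
  if (count_ops) attr(out, "ops") <- ops
  out
}

#' Dense quadratic oracle for flow-attention
#'
#' Mathematically identical output to [flow_attention_forward()], computed
#' by materialising the full n x n interaction matrix
#' \eqn{G = \phi(Q)\phi(K)^T} per head, at O(n^2) cost.  Used to verify the
#' linear implementation; never used in the model itself.
#'
#' @inheritParams flow_attention_forward
#' @return n x hid_dim output matrix.
#' @export
dense_flow_attention_oracle <- function(X, weights,
                                        config = flow_attention_config(),
                                        count_ops = FALSE) {
  if (any(!is.finite(X))) stop("non-finite values in flow-attention input")
  n <- nrow(X); d_in <- ncol(X)
  h <- config$hid_dim; nh <- config$num_heads
  dh <- h %/% nh
  ops <- 0
  Q <- X %*% weights$Wq; K <- X %*% weights$Wk; V <- X %*% weights$Wv
  ops <- ops + 3 * n * d_in * h
  R <- matrix(0, n, h)
  for (head in seq_len(nh)) {
    cols <- ((head - 1L) * dh + 1L):(head * dh)
    phiQ <- sigmoid(Q[, cols, drop = FALSE])
    phiK <- sigmoid(K[, cols, drop = FALSE])
    Vh <- V[, cols, drop = FALSE]
    G <- tcrossprod(phiQ, phiK)          # n x n interaction mass
    ops <- ops + n * n * dh + 2 * n * dh
    I <- rowSums(G)
    O <- colSums(G)
    O_prime <- colSums(G / I)
    ops <- ops + 4 * n * n
    A <- exp(O_prime - max(O_prime)); A <- A / sum(A)
    V_prime <- Vh * A
    I_prime <- rowSums(sweep(G, 2, O, `/`))
    ops <- ops + 2 * n * n + 3 * n + n * dh
    R[, cols] <- sigmoid(I_prime) * ((G / I) %*% V_prime)
    ops <- ops + n * n + n * n * dh + n * dh
  }
  out <- sweep(R %*% weights$Wo, 2, weights$bo, `+`)
  ops <- ops + n * h * h + n * h
  if (count_ops) attr(out, "ops") <- ops
  out
}

## ---- batched internals for training ---------------------------------------

# Stacked layout: token t of sample b sits at row b + B*(t-1) of a
# (B*n, d) matrix, matching the column-major collapse of (B, n, d).

flow_forward_batch <- function(x, w, config) {
  d <- dim(x); B <- d[1]; n <- d[2]
  h <- config$hid_dim; nh <- config$num_heads
  dh <- h %/% nh
  xf <- flatten23(x)
  Q <- xf %*% w$Wq; K <- xf %*% w$Wk; V <- xf %*% w$Wv
  R <- matrix(0, B * n, h)
  hc <- vector("list", B * nh)   # per-sample, per-head caches
  for (head in seq_len(nh)) {
    cols <- ((head - 1L) * dh + 1L):(head * dh)
    P <- sigmoid(Q[, cols, drop = FALSE])
    S <- sigmoid(K[, cols, drop = FALSE])
    Vh <- V[, cols, drop = FALSE]
    for (b in seq_len(B)) {
      rows <- seq(b, by = B, length.out = n)
      Pb <- P[rows, , drop = FALSE]
      Sb <- S[rows, , drop = FALSE]
      Vb <- Vh[rows, , drop = FALSE]
      I <- drop(Pb %*% colSums(Sb))
      O <- drop(Sb %*% colSums(Pb))
      Pn <- Pb / I
      Op <- drop(Sb %*% colSums(Pn))
      A <- exp(Op - max(Op)); A <- A / sum(A)
      Vp <- Vb * A
      Sn <- Sb / O
      Ip <- drop(Pb %*% colSums(Sn))
      gate <- sigmoid(Ip)
      Tm <- crossprod(Sb, Vp)
      U <- Pn %*% Tm
      R[rows, cols] <- gate * U
      hc[[(head - 1L) * B + b]] <-
        list(P = Pb, S = Sb, V = Vb, I = I, O = O, Pn = Pn, A = A,
             Vp = Vp, Sn = Sn, gate = gate, Tm = Tm, U = U)
    }
  }
  out <- sweep(R %*% w$Wo, 2, w$bo, `+`)
  dim(out) <- c(B, n, h)
  list(out = out, cache = list(xf = xf, R = R, hc = hc, B = B, n = n))
}

flow_backward_batch <- function(dy, w, config, cache) {
  B <- cache$B; n <- cache$n
  h <- config$hid_dim; nh <- config$num_heads
  dh <- h %/% nh
  dyf <- dy; dim(dyf) <- c(B * n, h)
  dWo <- crossprod(cache$R, dyf)
  dbo <- colSums(dyf)
  dR <- dyf %*% t(w$Wo)
  dQ <- matrix(0, B * n, h)
  dK <- matrix(0, B * n, h)
  dV <- matrix(0, B * n, h)
  for (head in seq_len(nh)) {
    cols <- ((head - 1L) * dh + 1L):(head * dh)
    for (b in seq_len(B)) {
      rows <- seq(b, by = B, length.out = n)
      cc <- cache$hc[[(head - 1L) * B + b]]
      dRb <- dR[rows, cols, drop = FALSE]
      # gate and aggregation
      dU <- dRb * cc$gate
      dgate <- rowSums(dRb * cc$U)
      dIp <- dgate * cc$gate * (1 - cc$gate)
      dPn <- dU %*% t(cc$Tm)
      dTm <- crossprod(cc$Pn, dU)
      dS <- cc$Vp %*% t(dTm)
      dVp <- cc$S %*% dTm
      # allocation normalisation (Sn = S/O, w = colSums(Sn), Ip = P w)
      dP <- outer(dIp, colSums(cc$Sn))
      dwv <- drop(crossprod(cc$P, dIp))
      dSn <- matrix(dwv, n, dh, byrow = TRUE)
      dS <- dS + dSn / cc$O
      dO <- -rowSums(dSn * cc$S) / cc$O^2
      # competition (Vp = A * V, A = softmax(Op), Op = S u, u = colSums(Pn))
      dA <- rowSums(dVp * cc$V)
      dV[rows, cols] <- dVp * cc$A
      dOp <- cc$A * (dA - sum(dA * cc$A))
      du <- drop(crossprod(cc$S, dOp))
      dS <- dS + outer(dOp, colSums(cc$Pn))
      dPn <- dPn + matrix(du, n, dh, byrow = TRUE)
      # Pn = P / I
      dP <- dP + dPn / cc$I
      dI <- -rowSums(dPn * cc$P) / cc$I^2
      # O = S colSums(P)
      dS <- dS + outer(dO, colSums(cc$P))
      dP <- dP + matrix(drop(crossprod(cc$S, dO)), n, dh, byrow = TRUE)
      # I = P colSums(S)
      dP <- dP + outer(dI, colSums(cc$S))
      dS <- dS + matrix(drop(crossprod(cc$P, dI)), n, dh, byrow = TRUE)
      # sigmoid maps
      dQ[rows, cols] <- dP * cc$P * (1 - cc$P)
      dK[rows, cols] <- dS * cc$S * (1 - cc$S)
    }
  }
  dxf <- dQ %*% t(w$Wq) + dK %*% t(w$Wk) + dV %*% t(w$Wv)
  list(dx = unflatten23(dxf, B, n),
       grads = list(Wq = crossprod(cache$xf, dQ),
                    Wk = crossprod(cache$xf, dK),
                    Wv = crossprod(cache$xf, dV),
                    Wo = dWo, bo = dbo))
}
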