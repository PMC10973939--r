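# Full model: one-hot input -> AAConv -> three CNN fusion stages
# (valid conv, maxpool 2/2, batch-norm, dropout) -> flow-attention ->
# three-layer MLP with softmax output.

CHECKPOINT_VERSION <- "acpflow-checkpoint-1"

#' Model configuration
#'
#' Defaults reproduce the published architecture: AAConv with 100 output
#' channels (kernel 10, 1 head), CNN stages (32, k8), (48, k5), (96, k3)
#' with dropout 0.2 after the last two, flow-attention with hidden dim 44,
#' 4 heads and dropout 0.05, and an MLP head 256 -> 48 -> 2 with dropout
#' 0.2 after each hidden layer.  Kernel sizes must decrease strictly down
#' the CNN stack (large receptive fields first, fine-grained last).
#'
#' @param max_len Padded peptide length, default 50.
#' @param aaconv An [aaconv_config()].
#' @param cnn_stages List of c(out_channels, kernel_size) per stage.
#' @param stage_dropout Dropout ratio after each stage.
#' @param flow A [flow_attention_config()].
#' @param mlp_widths MLP layer widths; last must be 2.
#' @param mlp_dropout Dropout after each hidden MLP layer.
#' @param seed Integer seed for parameter initialisation.
#' @return List of class \code{model_config}.
#' @export
model_config <- function(max_len = 50L,
                         aaconv = aaconv_config(),
                         cnn_stages = list(c(32L, 8L), c(48L, 5L),
                                           c(96L, 3L)),
                         stage_dropout = c(0, 0.2, 0.2),
                         flow = flow_attention_config(),
                         mlp_widths = c(256L, 48L, 2L),
                         mlp_dropout = c(0.2, 0.2),
                         seed = 1L) {
  ks <- vapply(cnn_stages, `[`, numeric(1), 2)
  if (any(diff(ks) >= 0))
    stop("CNN kernel sizes must be strictly decreasing, got: ",
         paste(ks, collapse = ", "))
  if (tail(mlp_widths, 1) != 2L)
    stop("final MLP width must be 2 (binary softmax head)")
  dr <- c(stage_dropout, mlp_dropout, flow$dropout)
  if (any(dr < 0 | dr >= 1)) stop("all dropout ratios must lie in [0, 1)")
  if (length(stage_dropout) != length(cnn_stages))
    stop("need one stage_dropout entry per CNN stage")
  structure(list(max_len = as.integer(max_len), alphabet_size = 21L,
                 aaconv = aaconv, cnn_stages = cnn_stages,
                 stage_dropout = stage_dropout, flow = flow,
                 mlp_widths = as.integer(mlp_widths),
                 mlp_dropout = mlp_dropout, seed = as.integer(seed)),
            class = "model_config")
}

# Trace position counts through the stack; errors early on impossible shapes.
model_dims <- function(config) {
  L <- config$max_len
  stage_L <- integer(0)
  for (s in config$cnn_stages) {
    L <- L - s[2] + 1L
    if (L < 1L) stop("kernel size ", s[2], " too large for ", L + s[2] - 1L,
                     " positions")
    L <- L %/% 2L
    if (L < 1L) stop("pooling collapsed the sequence to zero positions")
    stage_L <- c(stage_L, L)
  }
  list(stage_L = stage_L, n_tokens = L,
       flat_dim = L * config$flow$hid_dim)
}

#' Build the model
#'
#' Initialises all parameters deterministically under the config seed and
#' validates that adjacent layer shapes are compatible.
#'
#' @param config A [model_config()].
#' @return Object of class \code{acpflow_model}: list with \code{params}
#'   (nested arrays), \code{config}, \code{dims} and \code{n_params}.
#' @export
build_model <- function(config = model_config()) {
  dims <- model_dims(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  stages <- list()
  in_ch <- config$aaconv$out_channels
  for (i in seq_along(config$cnn_stages)) {
    s <- config$cnn_stages[[i]]
    stages[[i]] <- list(conv = conv1d_init(in_ch, s[1], s[2]),
                        bn = batchnorm_init(s[1]))
    in_ch <- s[1]
  }
  w <- config$mlp_widths
  params <- list(
    aaconv = aaconv_init(config$alphabet_size, config$aaconv),
    stages = stages,
    flow = flow_attention_init(in_ch, config$flow),
    mlp = list(l1 = linear_init(dims$flat_dim, w[1]),
               bn1 = batchnorm_init(w[1]),
               l2 = linear_init(w[1], w[2]),
               bn2 = batchnorm_init(w[2]),
               l3 = linear_init(w[2], w[3], gain = 1)))
  n_params <- 0
  tree_map(function(p) n_params <<- n_params + length(p), params)
  structure(list(params = params, config = config, dims = dims,
                 n_params = n_params),
            class = "acpflow_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.acpflow_model <- function(x, ...) {
  cat("acpflow model:", x$n_params, "parameters;",
      x$dims$n_tokens, "tokens x", x$config$flow$hid_dim,
      "features into the MLP head\n")
  invisible(x)
}

## ---- full forward / backward ----------------------------------------------

# x: (B, max_len, 21).  Returns logits plus caches for backprop; params are
# returned because batch-norm running statistics update during training.
model_forward_batch <- function(params, config, dims, x, training = FALSE) {
  B <- dim(x)[1]
  cache <- list()
  aa <- aaconv_forward_batch(x, params$aaconv, config$aaconv)
  cache$aaconv <- aa$cache
  hcur <- aa$out
  cache$stages <- list()
  for (i in seq_along(config$cnn_stages)) {
    st <- list()
    cv <- conv1d_forward(hcur, params$stages[[i]]$conv, "valid")
    st$conv <- cv$cache
    mp <- maxpool2_forward(cv$out)
    st$pool <- mp$cache
    L <- dim(mp$out)[2]; C <- dim(mp$out)[3]
    bn <- batchnorm_forward(flatten23(mp$out), params$stages[[i]]$bn,
                            training)
    params$stages[[i]]$bn <- bn$par
    st$bn <- bn$cache
    hcur <- unflatten23(bn$out, B, L)
    dp <- dropout_forward(hcur, config$stage_dropout[i], training)
    st$drop <- dp$cache
    hcur <- dp$out
    st$L <- L; st$C <- C
    cache$stages[[i]] <- st
  }
  fl <- flow_forward_batch(hcur, params$flow, config$flow)
  cache$flow <- fl$cache
  fd <- dropout_forward(fl$out, config$flow$dropout, training)
  cache$flow_drop <- fd$cache
  z <- fd$out
  dim(z) <- c(B, dims$flat_dim)
  l1 <- linear_forward(z, params$mlp$l1); cache$l1 <- l1$cache
  bn1 <- batchnorm_forward(l1$out, params$mlp$bn1, training)
  params$mlp$bn1 <- bn1$par; cache$bn1 <- bn1$cache
  r1 <- relu_forward(bn1$out); cache$r1 <- r1$cache
  d1 <- dropout_forward(r1$out, config$mlp_dropout[1], training)
  cache$d1 <- d1$cache
  l2 <- linear_forward(d1$out, params$mlp$l2); cache$l2 <- l2$cache
  bn2 <- batchnorm_forward(l2$out, params$mlp$bn2, training)
  params$mlp$bn2 <- bn2$par; cache$bn2 <- bn2$cache
  r2 <- relu_forward(bn2$out); cache$r2 <- r2$cache
  d2 <- dropout_forward(r2$out, config$mlp_dropout[2], training)
  cache$d2 <- d2$cache
  l3 <- linear_forward(d2$out, params$mlp$l3); cache$l3 <- l3$cache
  list(logits = l3$out, cache = cache, params = params, B = B)
}

bn_zero_grads <- function(bn_grads) {
  list(gamma = bn_grads$gamma, beta = bn_grads$beta,
       run_mean = bn_grads$gamma * 0, run_var = bn_grads$gamma * 0)
}

model_backward_batch <- function(params, config, dims, fw, dlogits) {
  cache <- fw$cache
  B <- fw$B
  b3 <- linear_backward(dlogits, params$mlp$l3, cache$l3)
  dd2 <- dropout_backward(b3$dx, cache$d2)
  dr2 <- relu_backward(dd2, cache$r2)
  bb2 <- batchnorm_backward(dr2, params$mlp$bn2, cache$bn2)
  b2 <- linear_backward(bb2$dx, params$mlp$l2, cache$l2)
  dd1 <- dropout_backward(b2$dx, cache$d1)
  dr1 <- relu_backward(dd1, cache$r1)
  bb1 <- batchnorm_backward(dr1, params$mlp$bn1, cache$bn1)
  b1 <- linear_backward(bb1$dx, params$mlp$l1, cache$l1)
  dz <- b1$dx
  n_tok <- dims$n_tokens
  dim(dz) <- c(B, n_tok, config$flow$hid_dim)
  dz <- dropout_backward(dz, cache$flow_drop)
  bf <- flow_backward_batch(dz, params$flow, config$flow, cache$flow)
  dh <- bf$dx
  stage_grads <- vector("list", length(config$cnn_stages))
  for (i in rev(seq_along(config$cnn_stages))) {
    st <- cache$stages[[i]]
    dh <- dropout_backward(dh, st$drop)
    dflat <- dh; dim(dflat) <- c(B * st$L, st$C)
    bb <- batchnorm_backward(dflat, params$stages[[i]]$bn, st$bn)
    dpool <- unflatten23(bb$dx, B, st$L)
    dconv_out <- maxpool2_backward(dpool, st$pool)
    bc <- conv1d_backward(dconv_out, params$stages[[i]]$conv, st$conv)
    stage_grads[[i]] <- list(conv = bc$grads, bn = bn_zero_grads(bb$grads))
    dh <- bc$dx
  }
  ba <- aaconv_backward_batch(dh, params$aaconv, config$aaconv,
                              cache$aaconv)
  list(aaconv = ba$grads,
       stages = stage_grads,
       flow = bf$grads,
       mlp = list(l1 = b1$grads, bn1 = bn_zero_grads(bb1$grads),
                  l2 = b2$grads, bn2 = bn_zero_grads(bb2$grads),
                  l3 = b3$grads))
}

#' Predict class probabilities for encoded peptides
#'
#' Runs the model in evaluation mode (dropout off, batch-norm running
#' statistics frozen), so the output is a pure function of parameters and
#' input.
#'
#' @param model An \code{acpflow_model}.
#' @param records Peptide data.frame, or a pre-encoded (n, max_len, 21)
#'   array.
#' @param alphabet Alphabet used for encoding.
#' @return data.frame with columns \code{id}, \code{p_acp},
#'   \code{p_non_acp} (summing to 1) and \code{predicted_label} (argmax;
#'   1 = ACP).
#' @export
predict_peptides <- function(model, records, alphabet = aa_alphabet()) {
  if (is.array(records) && length(dim(records)) == 3L) {
    x <- records
    ids <- paste0("peptide_", seq_len(dim(x)[1]))
  } else {
    x <- encode_dataset(records, alphabet, model$config$max_len)
    ids <- records$id
  }
  probs <- model_probs(model, x)
  data.frame(id = ids, p_acp = probs[, 1], p_non_acp = probs[, 2],
             predicted_label = as.integer(probs[, 1] >= probs[, 2]),
             stringsAsFactors = FALSE)
}

# Eval-mode probabilities, chunked so memory stays bounded.
model_probs <- function(model, x, chunk = 256L) {
  n <- dim(x)[1]
  out <- matrix(0, n, 2)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- model_forward_batch(model$params, model$config, model$dims,
                              x[idx, , , drop = FALSE], training = FALSE)
    out[idx, ] <- softmax_rows(fw$logits)
  }
  out
}

## ---- checkpointing ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes the parameter blob to \code{path} and a human-readable YAML
#' sidecar (\code{path.meta.yaml}) with the format version, config, seed
#' and alphabet order.
#'
#' @param model An \code{acpflow_model}.
#' @param path Checkpoint path.
#' @param alphabet Alphabet the model was trained with.
#' @export
save_checkpoint <- function(model, path, alphabet = aa_alphabet()) {
  saveRDS(model$params, path)
  meta <- list(format_version = CHECKPOINT_VERSION,
               package_version = as.character(utils::packageVersion("acpflow")),
               seed = model$config$seed,
               alphabet = paste(alphabet$symbols, collapse = ""),
               n_params = model$n_params,
               config = unclass_config(model$config))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$aaconv <- unclass(out$aaconv)
  out$flow <- unclass(out$flow)
  out
}

reclass_config <- function(lst) {
  lst$aaconv <- structure(lst$aaconv, class = "aaconv_config")
  lst$flow <- structure(lst$flow, class = "flow_attention_config")
  lst$cnn_stages <- lapply(lst$cnn_stages, unlist)
  structure(lst, class = "model_config")
}

#' Load a model checkpoint
#'
#' Refuses checkpoints whose sidecar is missing or carries a different
#' format version.
#'
#' @param path Checkpoint path written by [save_checkpoint()].
#' @return An \code{acpflow_model}.
#' @export
load_checkpoint <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("checkpoint or sidecar missing at ", path)
  meta <- yaml::read_yaml(meta_path)
  if (!identical(meta$format_version, CHECKPOINT_VERSION))
    stop("checkpoint format version '", meta$format_version,
         "' does not match '", CHECKPOINT_VERSION, "'")
  config <- reclass_config(meta$config)
  params <- readRDS(path)
  dims <- model_dims(config)
  n_params <- 0
  tree_map(function(p) n_params <<- n_params + length(p), params)
  structure(list(params = params, config = config, dims = dims,
                 n_params = n_params),
            class = "acpflow_model")
}
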