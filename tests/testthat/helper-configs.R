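# Shared miniature configurations: small enough for fast tests and
# finite-difference gradient checks, while exercising every layer type.
# max_len 30 gives two tokens after the CNN stack, so flow-attention sees
# more than one position.

tiny_model_config <- function(seed = 3L) {
  model_config(
    max_len = 30L,
    aaconv = aaconv_config(out_channels = 8L, kernel_size = 3L,
                           attn_channels = 4L, num_heads = 2L),
    cnn_stages = list(c(6L, 4L), c(8L, 3L), c(10L, 2L)),
    stage_dropout = c(0, 0, 0),
    flow = flow_attention_config(hid_dim = 8L, num_heads = 2L,
                                 dropout = 0),
    mlp_widths = c(12L, 6L, 2L),
    mlp_dropout = c(0, 0),
    seed = seed)
}

tiny_generator <- function(n_pos, n_neg, seed = 1L, ...) {
  generator_config(n_pos = n_pos, n_neg = n_neg,
                   length_range = c(10L, 30L), seed = seed, ...)
}

rand_mat <- function(n, d, seed) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# background distribution avoiding the residues of the default motif, so
# motif presence alone separates the classes exactly
disjoint_background <- function(motif = "FAKKLAKLAL") {
  aa <- acpflow:::STANDARD_AA
  used <- unique(strsplit(motif, "")[[1]])
  p <- stats::setNames(as.numeric(!(aa %in% used)), aa)
  p / sum(p)
}
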