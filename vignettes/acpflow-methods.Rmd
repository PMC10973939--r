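---
title: "Methods: flow-attention peptide classification in acpflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-attention peptide classification in acpflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpflow)
```

## The problem and the model

Anticancer peptides (ACPs) are short (4–50 aa) cationic peptides whose
activity correlates with conserved sequence motifs, in real training
collections predominantly located near the N-terminus and typically
covering more than half the sequence. `acpflow` classifies peptides
into ACP / non-ACP with a network whose parts map onto that biology:
convolution for local composition, self-attention for long-range
interactions (AAConv), a shrinking-kernel CNN stack for multi-scale
fusion, flow-attention for global feature interaction at linear cost,
and a softmax MLP head.

### One-hot encoding

Each residue becomes a 21-dimensional unit indicator (20 amino acids
plus the pad symbol `O`); a peptide is a 50×21 binary matrix.  The
default column order is alphabetical with the pad last, and the order
is a configurable field of `aa_alphabet()` — every encoding invariant
(unit rows, 21 columns, exact argmax round trip, injectivity) is
order-independent, so a different convention merely permutes columns.
Padding is on the right: sequences stay left-aligned, so the
N-terminal positions — where discriminating motifs concentrate — share
coordinates across peptides.  Ambiguous residues (B, J, U, X, Z) are
rejected rather than imputed; curated ACP collections contain only
standard residues, and silent imputation would let corrupt inputs
through.

### AAConv

The convolution branch uses 'same' zero padding.  This is forced by
the architecture rather than chosen freely: the layer concatenates the
convolution and attention branches position-wise, and with a width-10
kernel a 'valid' convolution would lose 9 positions and the
concatenation would be ill-formed.  The published total of 100 output
channels is taken as the concatenated total and split 80 convolution /
20 attention — attention *augments* convolution here, so it takes the
minority share; both numbers are configurable.  The per-head key depth
defaults to attention channels / heads.  No positional encoding is
added, so the attention branch alone is exactly equivariant under
position permutations (a property the tests exploit).

### Flow-attention

Queries and keys are mapped through a sigmoid into (0,1), making every
interaction mass `φ(Q_i)·φ(K_j)` strictly positive.  With

- incoming flow `I_i = φ(Q_i)·Σ_j φ(K_j)` (at sinks/queries),
- outgoing flow `O_j = φ(K_j)·Σ_i φ(Q_i)` (at sources/keys),

conservation — each token exchanges exactly one unit of flow with the
rest of the network — is imposed by *dividing* queries by `I` and keys
by `O`.  We read the conserved-flow expressions as these
normalisations (`φ(Q_i)/I_i`, `φ(K_j)/O_j`): multiplication in their
place would not conserve anything, and the flow-network principle the
mechanism is derived from requires unit exchange.  Competition then
reweights values by `softmax(O′)` taken over the source axis, and
allocation gates the aggregated output by `Sigmoid(I′)`:

`R = Sigmoid(I′) ⊗ [(φ(Q)/I) (φ(K)ᵀ V′)]`.

Evaluating the bracket right-to-left — `φ(K)ᵀV′` is d×d — never forms
the n×m interaction matrix, which is what makes the cost linear in
sequence length.  `dense_flow_attention_oracle()` deliberately *does*
form it, computing every flow quantity as a row/column sum of
`G = φ(Q)φ(K)ᵀ`; the two routes agree to < 1e-5 on all tested sizes,
and an instrumented multiply–add counter confirms the linear-vs-
quadratic growth.  The hidden dimension (44) is split evenly across 4
heads; a single linear map produces the output `R′`, with dropout 0.05
during training only.  Pad positions are not masked — they carry the
`O` indicator and participate like any token, matching the upstream
design, and the network learns to discount them.

### CNN stack, head, and shapes

The fusion stages use 'valid' convolution (the representation is meant
to shrink), max-pooling with size and stride 2 (the conventional
halving), batch normalisation after each conv+pool pair, and ReLU
throughout.  From 50 positions the stack yields 43→21, 17→8, 6→3
positions, so flow-attention sees 3 tokens of 96 features and the MLP
receives 3×44 = 132 features.  Published prose mentions a 94×64
feature map, which cannot be reconciled with the printed
hyperparameters (hidden dim 44); the implementation derives and logs
actual shapes from the config instead of forcing those numbers.

### Training

The loss is softmax cross-entropy (the softmax output layer implies
it); the optimiser is Adam at learning rate 1e-3, batch size 64 by
default.  All forward and backward passes are hand-derived base-R
matrix code; the test suite checks every parameter group's analytic
gradient against central finite differences through the full network,
which would expose an error in any layer's backward pass.  Batch-norm
uses momentum 0.1 and eps 1e-5, with running statistics frozen in
evaluation mode, so evaluation is a pure function of parameters and
input.  Training, fold assignment, initialisation and dropout masks
are all governed by explicit seeds; identical seeds reproduce
identical fits bitwise.

## Evaluation protocol

`dataset_split()` holds out `floor(0.2·N)` records per class — with
859 per class this gives exactly 688/171, reproducing the benchmark
arithmetic.  `kfold_indices()` assigns each class round-robin to 5
folds in one continuous sequence, so fold sizes differ by at most one
overall *and* per class.  `train_model()` fits one model per fold,
reports held-out fold metrics as mean ± sd, then retrains on the full
training split; the retrained model is the one reported and saved
(fold models exist only to estimate generalisation).  Metrics follow
the confusion-matrix definitions (ACC, Sn, Sp, MCC); a zero
denominator yields NA plus an explicit flag for Sn/Sp and the
standard 0 for MCC, never a silent zero.  AUC is the Mann–Whitney
probability with ties counted half, computed from ranks, and is
cross-checked against an independent package implementation in the
tests; the decision threshold for the confusion counts is 0.5
(argmax), while AUC always uses raw probabilities.

## The synthetic generator

`generate_dataset()` plants a single motif instance in each positive
at a region drawn from {N-terminal, middle, C-terminal} with default
weights 100:54:2 — the relative frequencies of single-region motif
placements observed in real ACP training data.  Sequence length is
sampled *conditionally on motif length*: with probability 0.85 it is
at most twice the motif length, so at least 85% of positives have a
motif covering half the sequence or more, again mirroring the field
statistics.  Negatives are background-only draws of the same length
distribution (so length alone cannot separate the classes).  The
default background is uniform over the 20 residues; the default motif
`FAKKLAKLAL` is a 10-residue cationic-amphipathic pattern of the kind
enriched in real ACPs.  Label noise flips an exact fraction of labels
after generation.  Multi-region placements are expressible by planting
twice; decoy motifs in negatives are off by default.

What the generator does *not* emulate: real amino-acid composition
biases, charge/amphipathicity constraints, homology structure between
related peptides, and motif degeneracy (the planted motif is exact).
Passing the learnability tests therefore demonstrates that the
architecture and training loop can recover a strong positional signal
through the full pipeline — not that the model attains any particular
accuracy on real ACP benchmarks, whose signal is weaker and more
distributed.

## Numerical choices and problem sizes

Oracle-equivalence tolerance is 1e-5 absolute (double precision leaves
large headroom; the bound is deliberately loose enough to be stable
across BLAS implementations).  Conservation identities are asserted at
1e-6.  Finite-difference gradient checks use step 1e-5 with a relative
tolerance of 1e-4.  Batches with fewer than 2 rows are skipped during
training because batch statistics are undefined there.  The worked
examples and tests use a reduced protocol — e.g. the learnability
benchmark trains the full-size architecture on a 1,000-peptide dataset
(5-fold CV, 4 epochs, batch 32) — chosen as the smallest runs that
demonstrate the properties cleanly; all sizes scale up through the
configs.  Under 5% label noise the attainable AUC on noisy labels is
about 0.95 even for a perfect scorer; the observed ≈ 0.94 is
effectively ceiling performance.

## Known limitations

- Pure-R training is practical to a few thousand peptides; it is not
  a GPU replacement.
- The checkpoint parameter blob is an RDS file (the sidecar is
  readable YAML); checkpoints are not portable to other frameworks.
- Only binary classification is supported; no masking of pad tokens;
  no pretrained weights are shipped.
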