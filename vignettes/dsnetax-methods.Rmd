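---
title: "Species annotation of 16S rRNA genes with DSNetax: models and methods"
author: "DSNetax authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species annotation of 16S rRNA genes with DSNetax: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the statistical and
architectural choices, their defaults, and what the desk-scale tests do and
do not establish. The worked example with concrete numbers lives in the
README; nothing here asserts an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Setting

Full-length bacterial 16S rRNA genes (~1500 bp) are classified to species
rank against a SILVA-style reference: a FASTA of sequences keyed by Feature
ID and a two-column table mapping each ID to a seven-rank lineage
(`d__...; p__...; ...; s__...`). Three properties of such references drive
the design: extreme class imbalance (a few species hold hundreds of reads,
most hold one or two), high inter-sequence similarity, and sprinkled IUPAC
ambiguity codes. Sequences are normalized at read time — uppercased, RNA
`U` mapped to DNA `T` — so every downstream token is over
`{A,C,G,T}` plus the eleven ambiguity codes.

## Preprocessing model

**Ambiguity resolution.** Every ambiguity code is replaced by a base drawn
uniformly from its IUPAC set. This is a randomization, not an imputation:
the information the code withheld is not recoverable, and resolving
uniformly avoids biasing base composition. Positions holding `A/C/G/T` are
never touched and length is preserved (tested as an invariant).

**Abundance-based replication.** Species below the high-abundance threshold
(default 11 reads) are replicated with a total multiplier per read count:
1–2 reads → 12, 3–5 → 4, 6–10 → 2. "Total multiplier" is a deliberate
reading — a 2-read species yields 2 × 12 = 24 reads, not 2 + 12×2 — applied
uniformly; the conservation law
`|output| = Σ_species n · factor(n)` is enforced by a brute-force
enumeration oracle in the tests. Each copy re-resolves ambiguity codes
independently, so copies of ambiguity-free sequences are exact duplicates
while ambiguous ones differ at the resolved sites.

Replication happens **before** the train/test split by default, which
inflates train/test similarity for rare species — the method's published
long-tail behavior (tail accuracy above head accuracy) is largely a
consequence of this. Because the inflation is a property users may not
want, `balanceDataset()` can equally be run on the training part after
`stratifiedSplit()`; the default order matches the published pipeline.

**Stratified split.** Per species, `round(n · fraction)` records go to the
test set, clamped to `[1, n−1]`, so every species appears in both parts.
A species with a single record is an error that points the user at
`balanceDataset()` (whose factors guarantee ≥ 2). All preprocessing RNG
derives per-record/per-species streams from `(seed, key)` hashes, so
results are invariant to record order and byte-identical across reruns.

## Tokenization and vocabulary

Sequences become overlapping k-mers (stride 1): L bases → L − k + 1 tokens.
The vocabulary is all 4^k DNA k-mers in lexicographic order after five
special tokens with fixed ids (`[PAD]`=0, `[UNK]`=1, `[CLS]`=2, `[SEP]`=3,
`[MASK]`=4). Any k-mer containing a non-ACGT symbol encodes as `[UNK]`.
Default k = 3 follows the published ablation (k = 3 beat 4 and 5); k is a
config parameter throughout, capped at 8 as a memory guard (4^8 + 5
tokens).

## Masked-language-model embedder

The embedder is a BERT-style transformer encoder trained with the MLM
objective only — the next-sentence-prediction head of the original BERT is
removed, as single sequences have no sentence pairs. Defaults:

* `dModel` 32 at desk scale (the published embedder family uses 768; the
  geometry is identical and `dModel` is free),
* post-layer-norm blocks, ReLU feed-forward of width `ffnMult × dModel`,
* masking rate 0.15 with **span masking** of k contiguous tokens per pick
  (the DNA-language-model convention; with stride-1 k-mers a single masked
  token is trivially recoverable from its overlapping neighbours, so spans
  are what make the objective non-degenerate), switchable to single-token
  masking,
* Adam, with the learning rate and epochs in `trainEmbedder()`.

Chosen positions are replaced by `[MASK]` outright; the original BERT's
80/10/10 corruption mix matters for fine-tuning mismatch, which does not
arise here because the classifier consumes hidden states, not masked
inputs.

**Long sequences.** A 1500-bp gene yields ~1498 tokens against a 512-token
window. How the published pipeline bridged this is unstated; this package
chunks content ids into consecutive windows of `maxTokens − 2` (room for
`[CLS]`/`[SEP]`) sharing `overlap` ids (default 64), embeds windows
independently, and reassembles one row per token, averaging the duplicated
overlap rows. Chunk-and-reassemble is lossless on ids (property-tested) and
is documented as this package's choice, not a reproduced detail.

Three providers implement the same `embedIds()` surface: the trained MLM
encoder, an imported token→vector table (`readEmbeddingTable()`, for
vectors exported from any external DNA language model checkpoint), and a
deterministic hash table (`hashEmbedder()`) whose per-token Gaussian
vectors make tests and benchmarks fast and exactly reproducible.
Embeddings are computed once and frozen for classifier training, matching
the two-separate-models data flow.

## Deep–shallow classifier

The L′ × d embedding matrix is treated as a one-channel 2-D map (image
convention, matching the use of image backbones). Two branches run in
parallel:

**Deep branch.** A 3×3 stride-2 stem convolution, batch norm, ReLU and 2×2
max-pool, then four stages of Split-Attention blocks — 2, 3, 2, 2 blocks
with stride-2 transitions between stages — ending in global average
pooling. Each block computes, per cardinal group: a 1×1 conv to the stage
width C, a grouped 3×3 conv to C·radix channels, the sum U of the radix
splits, a squeeze (global pool) and a two-layer bottleneck MLP producing
attention logits, the **r-softmax** across the radix so weights sum to 1
for every channel (a sigmoid gate when radix = 1, which reduces the block
to squeeze-excitation — tested against an independent SE oracle), the
attention-weighted recombination of the splits, a 1×1 conv, batch norm, a
projection shortcut where shape changes, and a residual ReLU. The
vectorized implementation is verified to 1e-5 against a fully naive
per-group/per-radix loop oracle.

**Shallow branch.** Three (4 or 5 for the ablation) Conv3×3+ReLU layers,
width 64 (scaled), strides 2,2,1 so total downsampling stays at 4× —
shallow on purpose, to keep local detail that the deep branch's global
semantics discard.

**Fusion.** Globally pooled branch vectors are concatenated and passed
through a linear head (default); summation and a gated convex combination
are available behind `fusion=`. Concatenation is the default because the
published description ("combines", "integration") names no formula and
concatenation is the assumption-free choice.

Unstated hyperparameters are explicit engineering defaults, not reproduced
facts: stem width = first stage width; stage widths 64/128/256/512 scaled
by `widthScale`; cardinality 1, radix 2, reduction 4; He initialization;
batch norm momentum 0.1, eps 1e-5. Baseline variants share the machinery:
`cnn3` (3 Conv+ReLU), `resnet34` (plain residual blocks, stages 3,4,6,3),
`resnest` (deep branch alone).

Since no deep-learning framework is available in a plain R stack, all
layers are implemented in the package: hand-derived backward passes over
BLAS matrix products with Rcpp kernels for im2col/col2im/max-pool, verified
end-to-end against finite differences during development and against the
naive block oracles in the suite.

## Training and evaluation

Cross-entropy with Adam (default lr 1e-3, batch 32 — unstated in the
source method and logged in every manifest). The reference schedule is 60
epochs with no early stopping; the best-test-top-1 checkpoint is kept when
a test set is supplied. A non-finite loss aborts with diagnostics rather
than continuing.

`evaluateTopk()` reports top-k accuracy (true species among the k
highest-scoring labels; ties broken by ascending label id so predictions
are deterministic). Genus accuracy maps each predicted species to its genus
— genus top-k counts a hit when any top-k species belongs to the true
genus; the source reports genus top-1 only, so genus top-5 is computed here
and simply additional. `headTailEval()` partitions test records at
cutpoints (default 50/100/500) by their species' **training** read count —
the long-tail profile the model actually saw, computed after replication —
with HEAD = count ≥ cutpoint. Per-part accuracies weighted by part sizes
recompose the overall accuracy exactly (tested); empty parts are flagged
not-reported rather than scored zero, mirroring the omitted TAIL(<500)
cell. `subsampleTraining()` and `runAblation()` reproduce the
training-fraction and architecture-ablation designs at any scale.

## Synthetic communities

The generator emulates what makes the real reference hard: long highly
similar sequences, a long-tailed abundance profile, and compatible
ambiguity codes.

* **Taxonomy:** species fill genera round-robin; higher ranks nest genera.
* **References:** a random root is mutated down the tree (genus ancestors,
  then species). The per-lineage substitution rate q solves
  `2q(1−q) + (2/3)q² = divergence`, so the *expected* pairwise difference
  between sister species equals the configured divergence exactly (both
  lineages mutating the same site agree with probability 1/3). Genus
  ancestors use 2q, keeping cross-genus pairs clearly more distant.
* **Reads:** per-species counts follow a truncated Zipf
  (`maxCount · rank^−exponent`, clamped at `minCount`; exponent 2 by
  default, giving the steep head and a tail that reaches the 1–2 read
  replication band so preprocessing is fully exercised), or a fixed count
  for balanced benchmarks. Each read adds substitutions at `withinRate`
  (default 0.5%) and then, at `ambiguityRate` per base, replaces the base
  with an ambiguity code drawn among the codes *containing* it — so
  resolution is a noisy-recovery process with exactly-known per-site
  recovery probability 1/|set|, used as a Monte-Carlo oracle.
* Substitutions only, no indels: the pipeline never aligns, and equal
  lengths keep fixture assertions exact.

What the generator does **not** model: indels and chimeras, PCR/primer
artifacts, quality scores, conserved-vs-variable regional structure, and
real SILVA label noise. Passing the desk-scale suite therefore shows the
pipeline is correctly implemented and can learn well-separated communities;
it does not certify species-rank accuracy on real databases.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step takes an explicit seed; sub-streams are
  derived by a polynomial hash of `(seed, key)` folded into 31 bits, so
  results are order-invariant and identical across platforms with R's
  default RNG.
* Ties in top-k break by ascending label id; r-softmax subtracts per-channel
  maxima before exponentiation; cross-entropy clamps probabilities at
  1e-12.
* Degenerate inputs: sequences shorter than k tokenize to an empty stream
  with a warning; an empty window list never arises because chunking only
  triggers above capacity; species with one record fail the split with
  actionable advice; empty head/tail parts are flagged, not scored.
* Desk-scale problem sizes used by the suite and acceptance script (the
  package's own choice of test scale): communities of 3–20 species, reads
  of 60–400 bp (one 1498-token forward pass checks length-independence),
  embedding width 8–32, classifier widths 1/8–1/16 of the reference
  64–512, training runs of 2–40 epochs. The same configuration surface
  scales to the full published geometry (d = 768, widthScale 1, 60
  epochs), which is a GPU-scale undertaking outside the test suite.

## Known limitations

* The MLM embedder trains per-sequence without GPU batching; it is meant
  for desk-scale corpora and for validating the objective, with
  `readEmbeddingTable()` as the bridge to externally trained checkpoints.
* Batch-norm statistics come from minibatches during training and running
  averages at evaluation; very small evaluation batches of unusual inputs
  rely on those running averages being representative.
* The replicate-before-split default reproduces the published protocol and
  its train/test similarity inflation for rare species; leakage-free
  evaluation requires splitting first, then balancing the training part.
* `resnet34` here uses 2-D convolutions over the embedding map; whether the
  published baseline used 1-D or 2-D convolutions is unstated.
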