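---
title: "Methods: heterogeneous-graph prediction of drug side effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous-graph prediction of drug side effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Model and assumptions

The package predicts drug–side-effect associations by fusing two
complementary signals. Drugs and side effects are the two node types of a
heterogeneous graph; within-type edges carry similarity weights in
\[0, 1\] and cross-type edges carry known associations. The central
assumptions are the standard ones of this model family: similar drugs
tend to share side effects; side effects sharing many causative drugs are
related; and the bipartite association pattern carries community
structure that node embeddings can capture.

Two graph views are built, one from chemical-substructure similarity and
one from disease-profile similarity, with the association matrix and
side-effect similarity shared. The adjacency matrix of each view doubles
as its node attribute matrix: node i's attribute row concatenates its
similarities to its own type with its associations to the other type.
Because the similarity diagonal is 1, the adjacency already contains
self-loops; no extra identity is added before the symmetric normalisation
`D^{-1/2} A D^{-1/2}`.

**Topology branch.** Per view, a two-layer graph-convolutional encoder
produces node embeddings and a two-layer graph-convolutional decoder
reconstructs the attribute matrix. A two-hidden-layer MLP discriminator
is trained against the autoencoder: original attribute rows are "true"
samples, reconstructed rows "false". The generator objective is the
adversarial term plus `gamma` (default 1) times the reconstruction error.
Per-view embeddings are fused by representation-level attention: a
feature-wise softmax of LeakyReLU scores weights each embedding, with the
raw embeddings added back as residuals. A pair's two fused rows are
stacked (2 × N_f) and passed through two convolution–pooling stages into
a softmax head.

**Attribute branch.** A pair's raw profile tensor (2 channels × 2 rows ×
(N_r + N_s)) is encoded by a self-calibrated convolution. The latent path
average-pools along the width (factor 4 by default), convolves (1 filter),
and maps back to full resolution by bilinear interpolation
(align-corners-false with edge clamping); the sum of the input and this
latent map passes through a logistic sigmoid to form a calibration gate
that multiplies the convolved input; a 32-filter convolution-pooling
stage fuses the calibrated map. A parallel path of two unpadded
convolutions (16, 32 filters) preserves edge information. The two maps
are center-cropped to a common width and concatenated channel-wise.

The final score is `lambda * p_topo + (1 - lambda) * p_att` on the
association probabilities, `lambda = 0.5` by default.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_f` | 32 | embedding width; 1500 is the full-scale setting at 4,900 nodes, 32 the desk-scale analogue |
| `encoder_dims` | (64, 32) | GCN encoder widths; decoder mirrors back to N_v |
| `disc_dims` | (64, 32) | discriminator hidden widths |
| `gan_epochs`, `gan_lr` | 200, 1e-3 | adversarial schedule (Adam) |
| `gamma` | 1 | weight of the reconstruction term in the generator loss |
| `head_epochs`, `head_lr`, `batch_size` | 100, 1e-3, 256 | branch-head schedule (Adam) |
| `latent_pool` | 4 | width downscale of the self-calibration latent path |
| `lambda` | 0.5 | fusion weight of the topology branch |
| filter counts | 16/32 (both conv stacks), 1 latent, 32 fusion | fixed architecture constants, 2 × 2 kernels |

All randomness flows from one integer seed; per-stage streams are derived
from it so adding a consumer never perturbs earlier draws.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` plants a block (community) structure: drugs and side
effects are partitioned into `n_blocks = 3` blocks; associations are
Bernoulli(0.5) within a block and Bernoulli(0.02) across. Each block owns
disjoint substructure and disease signature features; per-drug
memberships are flipped with probability 0.05, and similarities are
computed exactly as for real data (cosine for fingerprints, Jaccard for
sets, side-effect similarity from each side effect's realized drug set).
The default 60 × 120 scale trains the full model in minutes on one CPU.

This emulates the structural skeleton of pharmacological data — a sparse
bipartite matrix with correlated similarity matrices — but not its
realism: no fingerprint chemistry, no long-tailed side-effect frequency
distribution, no 1:36 class imbalance (the fixture's matrix is ~1:5,
about 1:19 among test pairs). A green
recovery test therefore establishes that the pipeline extracts planted
community signal end-to-end, not that it reproduces reference accuracy on
SIDER/CTD. Under this world the block-identity Bayes ceiling is around
0.86 AUC; the model exceeds it only by exploiting the realized
association noise, so test AUCs near 0.9 are the expected regime, not a
deficiency.

## Numerical choices

- **Set similarity.** The disease-set and drug-set similarity measure
  has no single standard form; the default is the Jaccard
  index, monotone in shared members and parameter-free, with a pluggable
  `measure` hook.
- **Cross-entropy.** A loss that paired `1 - y` with `log(1 - score_0)`
  would be degenerate, since the probability pair sums to one and that
  term equals `log(score_1)` — it would reward predicting positives
  always. The loss is standard binary cross-entropy on the association
  probability with `1e-12` clamping.
- **Generator adversarial term.** The minimax form saturates once the
  discriminator is ahead (its gradient vanishes as `p_true` for fake
  samples approaches 0), which at desk scale froze the game with the
  discriminator at ~100% accuracy. The non-saturating surrogate
  (minimise `-log D(fake)`) has the same fixed point and is used instead.
- **Reconstruction error** is the squared Frobenius distance per node
  (mean over nodes), keeping its gradient commensurate with the
  adversarial term for any graph size.
- **Discriminator granularity.** Flattening the full N_v × N_v matrix
  into one sample is intractable at full scale; each node's
  attribute row is one discriminator sample, mini-batched over nodes.
- **Pooling.** The latent-path downscale is average pooling as stated;
  the pooling type inside the conv-pooling stages is unspecified and is
  implemented as average pooling throughout, which keeps backpropagation
  a dense linear map.
- **Padding.** The original attribute path is unpadded (stated); the
  calibration and fusion convolutions use same-padding; on 2-row inputs
  no height padding is applied, so one 2 × 2 stage reduces height to 1
  and later stages use 1 × 2 kernels. The calibrated and original maps
  are center-cropped to the smaller width before concatenation.
- **Embedding standardisation.** Dense similarity graphs give GCN
  embeddings a dominant shared direction (within- vs cross-block cosine
  0.999 vs 0.959 on the fixture); each embedding column is z-scored
  before the attention/convolution head, which conditions the head
  without changing the information content. Dead (all-zero) ReLU columns
  pass through as zeros.
- **Attention parameters are shared across nodes** within a view (one
  weight matrix and bias per view); LeakyReLU slope 0.01.
- **Ties in rankings** are broken by side-effect index after score, so
  ranked outputs are deterministic.

## Design choices where the design was open

- **Stage-wise training.** The autoencoder/discriminator pair is trained
  first per view and frozen; the two scoring branches (attention, conv
  stacks, self-calibration, heads) are then trained jointly on the sum of
  the two cross-entropy losses, 1:1. End-to-end fine-tuning of the
  embeddings is out of scope.
- **Two distinct calibration parameter sets.** The calibration and fusion
  convolutions could in principle share parameters; weight tying would
  force artificial shape constraints, so they are independent (2-channel calibration conv, 32-filter fusion conv; the
  "1 and 32 filters" of the small feature space are the latent and fusion
  convolutions).
- **Ablations.** Disabling the topology branch scores with the attribute
  branch alone (`lambda` effectively 0); disabling the attribute branch
  scores with the topology branch (`lambda` 1); disabling
  representation-level attention reduces fusion to the residual sum
  `h_chem + h_dise`; disabling calibration routes the pair tensor through
  the unpadded original path only.
- **Recall@k aggregation** is per drug (each drug's test candidates are
  ranked, recall averaged over drugs with a test positive); a pooled mode
  exists behind a flag since either aggregation is defensible.
- **Cross-validation hygiene.** Held-out positive edges are zeroed in the
  association matrix before graphs and pair attributes are built, so no
  test signal leaks into training; similarities are left untouched.

## Limitations

- Validated on synthetic planted-structure data only; absolute reference
  metrics require the original SIDER/CTD matrices, which are not
  bundled.
- Training is dense-matrix CPU code; at full scale
  (4,900 nodes, millions of pairs) it would need a GPU framework — the
  desk-scale defaults are the supported regime.
- The discriminator never reaches the theoretical 50% equilibrium; its
  accuracy retreats from the peak toward chance, which is what the
  acceptance suite asserts.
- The adversarial game is logged (per-epoch losses, reconstruction error,
  discriminator accuracy) but no early stopping is applied; schedules are
  fixed-length for determinism.
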