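---
title: "Sparse convolutional autoencoders and the role of spatial context"
author: "pathae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse convolutional autoencoders and the role of spatial context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pathae)
```

## The problem

Tissue subtypes defined by molecular profiles often look alike at the
cell scale: their local structures — nuclei, boundaries, small texture
motifs — are nearly interchangeable, while the *spatial distribution* of
those structures over the tissue differs. A classifier restricted to a
small field of view then cannot beat chance, however good its features
are; the class only becomes visible once enough context is aggregated.
`pathae` implements a feature-learning and classification pipeline built
around exactly this premise, together with a synthetic generator that
reproduces the premise on demand so that every claim in this vignette is
checked by the package's own tests.

## The model

### Sparse convolutional autoencoder stages

One stage maps an $H \times W \times C$ image through a same-padded
convolution ($f \times f$ filters), a sigmoid, and $2 \times 2$ max
pooling to an $H/2 \times W/2 \times F$ encoding; the decoder unpools by
copying each value into its $2 \times 2$ block, applies a same-padded
deconvolution with filters of the same size, and a sigmoid. Training
minimizes

$$L \;=\; R \;+\; \lambda_s S, \qquad
R = \sum_{i}^{N} \bigl(x_i^{\text{out}} - x_i^{\text{in}}\bigr)^2,$$

where $S$ is the information entropy of the encoding activations: at
each spatial position the $F$ filter intensities are normalized to a
distribution $r_j$ and $-\sum_j r_j \ln r_j$ is accumulated over
positions (natural log, $0 \ln 0 := 0$, zero-total positions contribute
nothing). Minimizing $S$ pushes each position's activation mass onto few
filters — a sparsity pressure orthogonal to the reconstruction term.

Two readings of the entropy's outer sum are defensible (positions or
samples); we normalize **per spatial position across filters**, which
makes $S$ the sum of well-defined local entropies and gives a clean
per-position gradient
$\partial S/\partial z_j = -(\ln r_j + S_{\text{pos}})/t$.

Design choices the architecture does not dictate:

* **Nonlinearity.** Sigmoid on both encode and decode. The encoding must
  be nonnegative for the entropy to be defined, and reconstructions of
  $[0,1]$ images should be bounded; the sigmoid guarantees both.
* **Unpooling.** Plain copying, no pooling switches. This keeps stages
  self-contained (decoding needs no forward-pass bookkeeping).
* **Initialization.** Fan-in scaled uniform, seeded; Adam with step
  $10^{-3}$; $\lambda_s = 10^{-3}$ by default. With summed (not
  averaged) $R$, Adam's per-parameter normalization absorbs the scale.
* **Defaults for the 3-stage stack.** Filter sizes 7, 5, 3 and filter
  counts 16, 24, 32 per stage. Every pooling halves each spatial
  dimension, so two stages reduce the resolution to a quarter per axis.

Stacking is **greedy**: stage 1 trains on raw images and is frozen;
stage $k$ trains on stage-$(k{-}1)$ encodings. The tests assert bitwise
identity of earlier stages across later training — freezing is a
contract, not an intention.

### RISA layer

The reconstruction independent subspace analysis layer learns a filter
matrix $C$ ($k$ filters over $n$-dimensional flattened patches) under a
fixed binary pooling $H$ ($k/g$ consecutive, non-overlapping groups,
default size 2 — trained filters tend to pair up). The second-layer
output is

$$p_i(\mathbf{x}; C, H) = \sqrt{\sum_m H_{im}\Bigl(\sum_j C_{mj} x_j\Bigr)^2},$$

i.e. the Euclidean norm of each group's filter responses: nonnegative,
positively homogeneous, and invariant to rotations within a group —
which is the point: features become locally invariant. Training
minimizes $\sum_t \bigl(\tfrac1N \lVert C^{\mathsf T} C \mathbf{x}^{(t)}
- \mathbf{x}^{(t)}\rVert^2 + \lambda \sum_i p_i\bigr)$ over $C$ with $H$
fixed. For non-square $C$ the reconstruction only type-checks in the
$C^{\mathsf T} C$ order (the standard linear-autoencoder form), which is
what we implement; $N$ is read as the batch size. Applied to images, the
layer slides its patch window with stride 1 and same-style zero padding.

### Classifier variants

Three ways to couple features to a softmax head:

* **direct** — convolution+pool blocks trained jointly with the head
  (two blocks at 64 px, one more per doubling, one fewer per halving);
* **ae** — a greedy-pretrained stack as a *frozen* feature extractor;
* **risa** — a trained RISA layer applied convolutionally, frozen.

Freezing pretrained weights during supervised training is a choice the
architecture leaves open; we freeze by default (cheap heads, honest
attribution of what pretraining bought) and expose `fine_tune = TRUE`
for the autoencoder variant.

### The multi-reduction network for large images

Large images are cut into non-overlapping tiles, each tile encoded
independently by the frozen stack (zero padding per tile — tiles are
deliberately independent, at the cost of seam effects confined to a
filter-radius neighbourhood of tile borders), and the encoded tiles are
reassembled. The encoded map is split into $G \times G$ subpanes; **one
shared dense map** (sigmoid, $d_r = 24$ outputs) reduces every subpane —
equivalently a stride-$G$ window-$G$ convolution, an equivalence the
tests assert numerically — and a final dense layer maps the
concatenated $G^2 d_r$ values to class logits.

Because encoding activations ride on a large, nearly constant background
response, the shared map's inputs are standardized per dimension with
statistics estimated from the training features and stored on the
classifier. Without this the discriminative signal (a fraction of a
percent of the feature magnitude) leaves the softmax stuck at uniform;
with it the same optimizer fits in a few hundred steps.

We scale the subpane grid with the input ($G = $ encoded edge $/4$), so
the *shared* reducer sees identically-sized subpanes at every context
size and its parameter count is context-invariant; the final layer's
size necessarily grows with $G^2$. How a fully context-invariant node
count could be kept is not derivable from the architecture's published
description, so we fix the architecture per run instead.

## The synthetic generator

Classes share one **motif bank** (Gaussian cell-blobs, oriented stripes,
concentric rings, crosses; dark purplish tones on an eosin-pink
background with amplitude-0.05 smoothed noise) and one motif mix, and
differ **only in placement**:

* `uniform` — homogeneous Poisson at density $1.1 \times 10^{-3}$
  motifs/px² (about 72 motifs per 256² image);
* `clustered` — Neyman–Scott: Poisson parents, mean 9 offspring at
  Gaussian spread 10 px;
* `graded` — inhomogeneous Poisson with intensity rising linearly along
  a fixed direction (sampled by thinning), same mean density.

Overlapping stamps composite by per-pixel maximum, so order never
matters and values never wrap. These densities and spreads were chosen
once, at design time, to satisfy the generator's specified property —
8-px patch statistics statistically indistinguishable between classes
(two-sample KS, $p > 0.01$) while quadrat-count dispersion separates
them — and then frozen; the tests verify both sides.

What the generator does *not* emulate: stain variability, nucleus/stroma
morphology, imaging artifacts, scale heterogeneity. Passing the context
experiment shows the architecture aggregates spatial statistics it was
designed for; it does not certify performance on real slides.

## The context-size experiment

`context_size_experiment()` is the package's central study, scaled to a
desktop: 3 classes × 80 images at 256², a 3-stage stack pretrained on
64² crops of the training split (120 Adam steps per stage, batch 8),
then reduction classifiers trained on the encoded images at 32², 128²
and 256² context (800 steps, batch 16). Problem sizes were fixed once as
a realistic desk-scale study; the whole experiment runs in a few
minutes. The test suite asserts: full-context accuracy at least
90 %, the 32² context at least 20 points lower, and accuracy
non-decreasing in context within a 5-point tolerance. At the default
seed the run reports 35.4 / 70.8 / 95.8 % — small contexts hover near
chance because local patches genuinely carry almost no class signal.

## Numerical notes and limitations

* Convolutions are BLAS-backed im2col products; gradients are analytic
  and verified against finite differences and nested-loop oracles to
  $10^{-6}$ on small fixtures.
* Max-pool backprop routes gradients to the first maximum in row-major
  order on exact ties (measure-zero for continuous inputs).
* Entropy gradients clamp normalized intensities at $10^{-12}$; sigmoid
  encodings are strictly positive so the clamp is a guard, not a bias.
* Determinism: every seeded operation restores the caller's RNG state;
  identical seeds give bit-identical models on a fixed BLAS.
* Checkpoints are a single hierarchical RDS container (stage groups plus
  meta with a checked version field); corrupt or truncated files and
  version mismatches raise typed errors rather than partial models.
* Training is plain Adam without weight decay, batch norm, augmentation
  or early stopping; at the package's problem sizes the reducers can
  overfit a small training split, which is why the experiment uses 80
  images per class.
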