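---
title: "Joint affinity and binding-region prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint affinity and binding-region prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtamix)
```

## The problem

Drug–target affinity (DTA) prediction treats drug–protein interaction as a
regression task: given a small molecule (a SMILES string) and a protein
sequence, predict a continuous binding strength — pKd for Davis-style data,
the integrated KIBA score for KIBA-style data.  Models that *also* say
**where** on the protein the drug binds are far more useful to a bench
scientist than a bare number, but attention weights of a generic network are
a poor proxy for binding sites.  `dtamix` therefore couples the regression
with an explicitly *supervised* binding-region (BR) channel: a per-residue
**response vector** whose peak is the predicted region, trained against
interval-coded binding-site annotations.

## Model

Each entity is represented twice and the two views are fused:

* **Protein**: per-residue amino-acid tokens (22-symbol vocabulary: 20
  canonical residues, `X`, pad) and overlapping k-mer "word" tokens
  (k = 3 by default, frequency-built vocabulary with pad/OOV indices).  Both
  pass through learned embedding tables into `L_P x C_P` feature maps.
* **Drug**: a functional-class circular fingerprint (Morgan-style hashing
  seeded with pharmacophoric atom classes: donor, acceptor, aromatic,
  halogen, charge signs) and a molecular graph (atom feature rows plus a
  padded adjacency matrix with unit diagonal).

**Encoder blocks.** Every branch is encoded by a stack of residual
token-mixing blocks.  The *global extractor*

\[ X_{out} = X_{in} + AF_2\big(FC^{(3)}(AF_1(X_{in})^T)^T\big) \]

mixes information **along the length axis** (the three fully connected
layers act on positions, per channel; hidden width equals L), where
\(AF(X) = \mathrm{Diag}(\alpha)X + \beta\) is a trainable per-channel affine.
The *individual extractor* refines per-element features: for drugs a
channel-axis two-layer FC stack; for proteins three large-kernel grouped 1D
convolution blocks (kernel sizes applied in order, e.g. 7→15→31 at
benchmark scale), each followed by normalization and a rectifier.  Both are
wrapped in affines, gated by *spatial attention*
\(Att(X) = X \odot \sigma(\mathrm{CNN2D}(X))\) (a single-channel k×k 'same'
convolution over the L×C map, gating per position *and* channel), residual
added, and projected by a final FC.

**Fusion.** The two views of an entity are merged by a gated convex
combination:

\[ W_{att} = \sigma(\mathrm{CNN2D}(\mathrm{Concat}(X_1, X_2))), \qquad
   X_f = FC^{(1)}(X_1)\odot W_{att} + X_1 + FC^{(1)}(X_2)\odot(1-W_{att}) + X_2. \]

The concatenation enters the gate convolution as two *aligned input
channels* (one kernel per view, summed before the sigmoid): a single-channel
convolution over a width-concatenated `L x 2C_S` image could not return a
`L x C_S` gate, while the channel-stacked reading keeps the gate aligned
with corresponding channels of both views — which is exactly what "the
attention weight of view 1 versus view 2" means.  The two branch
projections do not share weights by default (`share_fc1` flag).

**Mix-decoder.** A learned linear layer collapses the drug feature matrix
into a kernel \(K = W_s^T F_d \in \mathbb{R}^{C_S\times C_S}\), which slides
along the protein map as a full-channel window,

\[ s_i = \sum_{m,n} K(m,n)\, F_p(i + m - \lfloor C_S/2\rfloor,\, n), \]

yielding the response vector `s` (length `L_P`, 'same' zero padding).  The
predicted region of scale S is the interval of length S centred on
`argmax(s)` (first maximum on ties), clipped to the sequence.  The decoder
then injects `s` back into the protein features (row-wise scaling), injects
graph connectivity into the drug features (row means of the adjacency),
enhances both with self-enhancement blocks
\(X W_1 \odot \mathrm{softmax}_{length}(X W_m / C_S)\), mixes them with a
cross-attention block over the row-concatenation, pools both axes to the
interaction vector (length `L_P + L_D + C_S`), and regresses affinity with
a three-layer FC head (dropout in training).

Two printed formulas needed repair, recorded here as package decisions: the
cross-attention mixing term is transposed back before the elementwise
product (the printed form is shape-inconsistent), and its softmax re-uses
`Wm1` (the block declares no third parameter matrix).

## Objective

The joint loss is

\[ \mathcal{L} = \mathrm{MSE}(\hat{a}, a) + \lambda_{BR}\cdot
   \tfrac1{L_P}\sum_i \mathrm{RWing}(s_i - y_i), \]

where `y` codes 0 off-site and the pair's affinity value on annotated site
residues, and RWing is the rectified Wing loss: identically zero on
`(-r, r)`, logarithmic `w·ln(1 + (|x|-r)/ε)` on `r ≤ |x| < w`, linear
`|x| - C` beyond, with `C = w - w·ln(1 + (w-r)/ε)` the unique constant
making the function continuous at `|x| = w`.  The dead zone ignores
annotation noise; the linear tail keeps the sparse, outlier-like on-site
targets from dominating as squared error would.

**Parameter defaults and a source discrepancy.** The loss's source states
w = 1, r = 3 — an ordering under which the logarithmic branch is empty and
the dead zone swallows the linear one, contradicting the branch domains.
The package requires `r < w` and defaults to **w = 3, r = 1, ε = 0.15**
(the only consistent reading of the printed branch structure);
`rwing_params()` rejects invalid sets rather than reordering silently.
`λ_BR` defaults to 1 (no weighting is stated anywhere).  Pairs without
annotations contribute only the MSE term.

## Training

AdamW (decoupled weight decay on weight matrices only), learning rate
5e-4, weight decay 1e-3, batch size 16, dropout 0.1 — the published recipe.
Minibatches average per-sample gradients from individual autodiff graphs.
Per epoch the trainer logs the joint training loss and validation MSE,
keeps the best-validation checkpoint and stops early (patience 20; the
epoch budget, never stated in the source, defaults to 200).  Everything
draws from one seeded RNG: initialization, shuffling, dropout — two runs
with the same seed produce bitwise-identical logs and predictions.

Two deliberate choices:

* the affinity-head output bias is initialized to the mean training
  affinity, so short trainings measure structure learning rather than
  offset learning;
* `selection = "best"` (validation-MSE checkpoint) is the benchmark
  protocol, but `selection = "final"` is available and used when the
  quantity of interest is the fully trained response mechanism: at desk
  scale the affinity head overfits within a few epochs, so the best-MSE
  checkpoint predates binding-region learning.

**Normalization.** The convolution blocks normalize per channel over the
length axis (population statistics of the sample itself, identical in
training and evaluation) instead of batch normalization: the trainer
processes per-sample graphs, where batch statistics would couple samples
and break determinism.  `use_norm = FALSE` disables it.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` plants the statistical structure the model assumes:
i.i.d. uniform residue sequences (150–200 aa) with exactly **one**
class-specific motif (8 residues, 4 classes, each class drawing from a
distinct reduced residue alphabet) at a recorded interval — the annotated
site; ~20 valid template molecules with substituent variation, each drug
carrying a motif-class profile; affinities
`5 + 2·1[drug class = motif class] + N(0, 0.2)`, clipped to pKd-like
[4, 10] (Davis labels concentrate near 5, hence the base).  A green test on
this world establishes that the *mechanism* works: featurization is
faithful, gradients flow, the supervised response vector localizes planted
signal well above the ~S/L_P chance level, metrics behave.  It does **not**
establish benchmark-level accuracy: real binding sites are not single exact
motifs, real affinity is not a two-level class function, and real chemical
similarity structure is far richer than a template pool.  The published
benchmark numbers require the external Davis/KIBA/sc-PDB downloads and
GPU-scale training, both out of scope here.

## Numerical choices

* Convolution kernels must be odd ('same' padding symmetric); the response
  window may be even (`C_S`), centred at `floor(C_S/2)`.
* Softmax is computed with a global max shift; `fa` columns sum to 1 within
  1e-6 (tested).
* Argmax ties resolve to the smallest index; region intervals are clipped,
  so a peak at the boundary yields a shorter interval.
* `rm²` floors `r² − r0²` at zero before the square root (the printed
  formula without the radical can be negative for perfect predictions).
* AUPR integrates step-wise over distinct prediction scores with ties
  grouped; a constant predictor scores exactly the positive prevalence.
* Davis-style binarization is strict (`pKd > 7`), KIBA-style inclusive
  (`score ≥ 12.1`), direction exposed as a flag.
* Coordinates are 0-based half-open (BED convention) end to end.

## Known limitations

* Per-sample training graphs make CPU cost linear in batch size; the
  benchmark-scale presets (`davis`, `kiba`) are provided and shape-tested
  but are not practical to train in this engine.
* The SMILES reader covers the organic subset plus bracket
  charge/H/isotope; stereochemistry is ignored and exotic valence states
  fall back to zero implicit hydrogens.  It is validated against a frozen
  external-toolkit reference on drug-like molecules.
* The k-mer vocabulary policy (k = 3, frequency cut) is a package choice;
  the source names "word embedding" without defining it.
* With multiple annotated sites per protein a predicted region counts as a
  hit if it covers *any* site residue.
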