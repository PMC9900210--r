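# dtamix

Joint drug–target binding **affinity** and binding-**region** prediction in R.

## What this is

Most drug–target affinity (DTA) models regress a binding strength — pKd for
Davis-style data, the KIBA score for KIBA-style data — from a SMILES string
and a protein sequence, and at best wave at attention weights when asked
*where* the drug binds. `dtamix` implements a multi-task architecture that
predicts both at once, with the binding region **supervised** by
interval-coded site annotations rather than inferred from attention:

* **Dual representations**: proteins as amino-acid tokens + overlapping
  k-mer tokens; drugs as functional-class circular fingerprints + molecular
  graphs (atom features, padded adjacency).
* **Token-mixing encoders**: residual blocks with a global extractor
  `X + AF(FC³(AF(X)ᵀ)ᵀ)` acting along the length axis, an individual
  extractor (channel-axis FC stack for drugs; large-kernel grouped 1D
  convolutions for proteins), and spatial-attention gates
  `X ⊙ σ(CNN2D(X))`.
* **Gated fusion** of the two views of each entity:
  `Xf = FC(X1)⊙W + X1 + FC(X2)⊙(1−W) + X2`, `W = σ(CNN2D(Concat(X1,X2)))`.
* **Mix-decoder**: a drug kernel `K = Wsᵀ Fd ∈ R^{C_S×C_S}` slides along the
  protein feature map, `s_i = Σ_{m,n} K(m,n)·Fp(i+m−⌊C_S/2⌋, n)`; the peak
  of this **response vector** centres the predicted region. Self-enhancement
  and cross-attention blocks mix the features; two-axis average pooling
  feeds a FC affinity head.
* **Joint objective**: `MSE(affinity) + λ·mean RWing(s − y)` where `y` is 0
  off-site and the pair's affinity on-site, and RWing is the rectified Wing
  loss — zero on `(−r, r)`, logarithmic on `[r, w)`, linear beyond, glued
  continuously (defaults `w = 3, r = 1, ε = 0.15`).
* **Evaluation**: concordance index (ties score 0.5), MSE, rm²
  (`r²(1−√(r²−r0²))`), AUPR under dataset thresholds (Davis pKd > 7,
  KIBA ≥ 12.1), and multi-scale binding-region hit accuracy (S = 5/10/15).

Because no deep-learning framework is available in the target R stack, the
model runs on a package-internal tape-based reverse-mode autodiff engine
(gradient-checked against finite differences) with Rcpp kernels for the
convolutions. A synthetic-data module generates planted-motif worlds so the
whole pipeline — training, localization, metrics — is exercisable on a
laptop CPU without any downloads.

## Worked example

```r
library(dtamix)

# 1. simulate a planted-motif world: 20 proteins x 6 drugs, 60 pairs
ds <- generate_dataset(sim_config(n_proteins = 20L, n_drugs = 6L,
                                  n_pairs = 60L, seed = 42L))

# 2. featurize and train a desk-scale model for 40 epochs
cfg <- dta_config("desk")
store <- featurize_dataset(ds$proteins, ds$drugs, cfg)
splits <- make_cv_splits(nrow(ds$affinities), test_fraction = 1/6, seed = 1L)
model <- train_dta(store, ds$affinities, cfg,
                   train_config(epochs = 40L, patience = Inf, seed = 1L,
                                selection = "final"),
                   splits[[1]])

# 3. predict affinity + binding regions for the held-out pairs
test <- ds$affinities[splits[[1]]$test_indices, ]
pred <- predict_dta(model, store, test)
head(pred[, c("drug_id", "protein_id", "pred_affinity", "peak_pos",
              "start_S15", "end_S15")], 4)
#>   drug_id protein_id pred_affinity peak_pos start_S15 end_S15
#> 1    D001       P019      5.455324       88        81      96
#> 2    D005       P020      5.452586       40        33      48
#> 3    D003       P006      5.453342       49        42      57
#> 4    D005       P007      5.458709      100        93     108

# 4. evaluate
sites <- lapply(ds$proteins, `[[`, "sites")
names(sites) <- vapply(ds$proteins, `[[`, "", "id")
rep <- evaluate_predictions(pred, ds$affinities, sites)
unlist(rep[c("ci", "mse", "rm2")])
#>        ci       mse       rm2
#> 0.2666667 1.0146081 0.1009593
rep$br_accuracy
#>  S5 S10 S15
#> 0.7 0.7 0.7
```

Reading the output: `peak_pos` is the argmax of the response vector
(0-based residue), `start_S15`/`end_S15` the 15-residue region around it
(half-open). After only 40 epochs on 50 training pairs the *region*
channel already covers 70% of true sites at every scale (chance at S = 15
on a 200-residue window is ≈ 0.075), while held-out *affinity* is still
near the label mean — with this little data the supervised localization
signal is learned much faster than generalizable affinity. The acceptance
suite trains the stated 200-pair world for 100 epochs and reaches S = 15
hit accuracy 1.0 on held-out pairs.

## Command line

```sh
inst/cli/dtamix simulate --out data/ --n-proteins 50 --n-drugs 10 --n-pairs 200 --seed 0
inst/cli/dtamix train --proteins data/proteins.fasta --drugs data/drugs.tsv \
    --affinities data/affinities.tsv --sites data/sites.tsv \
    --preset desk --epochs 100 --checkpoint model.rds
inst/cli/dtamix predict --checkpoint model.rds --proteins data/proteins.fasta \
    --drugs data/drugs.tsv --affinities data/affinities.tsv --out pred.tsv
inst/cli/dtamix evaluate --predictions pred.tsv --affinities data/affinities.tsv \
    --sites data/sites.tsv
```

## Files

* `R/` — autodiff engine, featurization (incl. an organic-subset SMILES
  reader validated against frozen external-toolkit references), encoder /
  fusion / mix-decoder blocks, losses, metrics, simulator, trainer, CLI.
* `src/conv_ops.cpp` — im2col/col2im and 2D-convolution kernels.
* `vignettes/dtamix-methods.Rmd` — the model, its assumptions, parameter
  defaults, numerical choices and known limitations.
* `tests/testthat/` — unit, property and oracle tests;
  `test-acceptance.R` holds the acceptance criteria.
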