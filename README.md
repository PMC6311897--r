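# scfp — SMILES convolution fingerprints and chemical motif detection

`scfp` learns a task-driven molecular fingerprint directly from SMILES
strings and explains it.  A compound's canonical SMILES is encoded as a
matrix of per-symbol feature vectors (21 atom features + 21 grammar
features), a one-dimensional convolutional network is trained on a binary
classification task (e.g. an assay outcome), and the 64-dimensional
global-max-pool layer output is the *SMILES convolution fingerprint*
(SCFP).  Because every fingerprint dimension is the maximum of one
convolution filter's activation map, dimensions that respond unusually
strongly (Z-score above 2.58 against a background set) can be traced back
through the network's receptive field to the SMILES substring — and the
atoms — that produced them.  The package calls these *chemical motifs*.

## The model

For a compound with SMILES symbols encoded as rows of
`X ∈ R^(max_len × 42)`:

```
X → conv(128 filters, width 7) → LeakyReLU → avg-pool(7)
  → conv(64 filters, width 7)  → LeakyReLU
  → global max over positions  →  SCFP f ∈ R^64
  → dense(96) → LeakyReLU → sigmoid → P(active)
```

A unit of the final map sees at most `2·k1 + k2 = 21` SMILES symbols at the
default window sizes `k1 = k2 = 7` — the maximum detectable motif size.
Motif calls use `z_j(x) = (f_j(x) − μ_j) / σ_j > 2.58` with `μ, σ`
estimated on a background dataset, and `traceback_span()` maps the
responsible filter's argmax position to the exact input interval.

Everything numerical (forward pass, backpropagation, Adam/AdaGrad) is
implemented in base R on BLAS matrix products; chemistry plumbing uses
Open Babel (canonicalization, ECFP baseline), ChemmineR (SDF), igraph
(substructure ground truth) and pROC (ROC-AUC).

## Quick start

```r
library(scfp)

# 1. a synthetic benchmark with a known planted substructure
d  <- generate_planted_dataset(scfp_gen_params(n_active = 30, n_inactive = 60, seed = 3))
fs <- featurize_dataset(d)

# 2. train
model <- build_model(scfp_model_config(), seed = 3)
fit   <- train_scfp(model, fs, config = scfp_train_config(epochs = 8, seed = 3))

# 3. fingerprints and motifs (background statistics from the inactives)
st   <- fit_filter_stats(fit$model, subset_featurized(fs, which(d$label == 0)))
hits <- detect_motifs(fit$model, subset_featurized(fs, which(d$label == 1)), st)
head(hits[, c("compound_id", "filter", "z", "substring")])
```

```
  compound_id filter        z           substring
1    cmpd0002     49 2.776483      )OOC(=O)C(=O)O
2    cmpd0018     49 2.945932      SC(C(=O)O)O)NC
3    cmpd0021     49 3.391442    CCCC(=O)O)O)N)Cl
4    cmpd0022     49 2.843113 =C(C(=O)O)OC)C(N1)C
```

After only 8 epochs the strongest filter already locks onto the planted
carboxy fragment `C(=O)O`.

The same pipeline is scriptable from the shell:

```sh
exec/scfp simulate --out sim.tsv --n-active 30 --n-inactive 60 --seed 3
exec/scfp train --in sim.tsv --model-out model.json --stats-out stats.json --epochs 8 --seed 3
exec/scfp motif --in sim.tsv --model model.json --stats stats.json --out motifs.tsv
exec/scfp fingerprint --in sim.tsv --model model.json --out fingerprints.tsv
```

See `vignettes/scfp-methods.Rmd` for the model's assumptions, parameter
defaults and their rationale, and the limits of the synthetic generator.

## License

MIT (see `LICENSE`).
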