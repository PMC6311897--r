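---
title: "SCFP methods: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SCFP methods: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfp)
```

# Overview

`scfp` learns a *SMILES convolution fingerprint* (SCFP): a task-driven,
64-dimensional real-valued descriptor of a chemical compound, produced by a
one-dimensional convolutional network that reads the compound's canonical
SMILES string symbol by symbol.  Because every fingerprint dimension is the
global maximum of one convolution filter's activation map, a strongly
responding dimension can be traced back to the contiguous stretch of SMILES
symbols — and hence atoms — that produced it.  The package calls such a
stretch a *chemical motif*.

The pipeline is:

1. **Canonicalize** the SMILES (Open Babel, Kekulé form).
2. **Tokenize** into atom and grammar symbols; **featurize** each symbol as a
   42-dimensional vector.
3. **Learn** the network on a binary classification task (e.g. an assay
   outcome) by mini-batch gradient descent.
4. **Detect motifs** by Z-scoring each fingerprint dimension against a
   background set and tracing high scores back through the receptive field.

# Input representation

## Canonical Kekulé SMILES

One molecule must map to one string, so all input passes through Open
Babel's canonical SMILES writer.  We use the Kekulé form (no lowercase
aromatic atoms): aromaticity is not discarded but moved into a per-atom
feature, which keeps the symbol alphabet small and uniform.  The writer's
canonical Kekulé string depends on whether the input was spelled aromatic
or Kekulé, so `canonicalize_smiles()` makes two passes — first to the
canonical aromatic form, then Kekulizing that — which makes the result
independent of the input spelling and idempotent.

## Feature matrix

A compound with $L$ SMILES symbols becomes a matrix
$X \in \mathbb{R}^{\text{max\_len} \times 42}$, zero-padded below row $L$.
Each row is one symbol:

* **Atom symbols** (columns 1–21): atom-type one-hot over
  $\{H, C, O, N, \text{other}\}$; hydrogen count; degree; formal charge;
  valence; ring membership; aromaticity; chirality one-hot over
  $\{R, S, \text{other}\}$; hybridization one-hot over
  $\{s, sp, sp^2, sp^3, sp^3d, sp^3d^2, \text{other}\}$.
* **Grammar symbols** (columns 22–42): a one-hot over the 21 SMILES
  grammar classes (branches, brackets, bond symbols, cis/trans, chirality
  marks, charges 2–7, ring starts/ends, ionic bonds).

`max_len` defaults to 400 rows, large enough for drug-like compounds; when
`featurize_dataset()` is given no configuration it instead uses the
dataset-wide maximum token count, which avoids wasting compute on padding
for small studies.

### Atom-perception assumptions

Atom properties are derived directly from the parsed SMILES graph rather
than from a 3-D structure:

* *Implicit hydrogens* follow the smallest standard valence of each
  element (C:4, N:3, O:2, halogens:1, …).
* *Hybridization* uses the steric-number rule (σ-neighbours + lone pairs):
  2 → sp, 3 → sp², 4 → sp³, etc.  This deliberately does **not** promote
  conjugated heteroatoms (ester oxygens, amide nitrogens) to sp² the way
  some toolkits do; the rule is simple, deterministic and documented, and
  the network can learn any residual signal from the neighbouring symbols.
* *Chirality* (R/S) is computed from the SMILES `@`/`@@` parity with a
  simplified CIP priority: substituents are ranked by breadth-first spheres
  of atomic numbers (duplicated for multiple bonds) up to depth 6.  True
  CIP tie-breaking rules beyond that depth, and stereo descriptors other
  than tetrahedral R/S, are reported as "other".  Cross-toolkit tests pin
  the common cases.

These are per-atom *features*, not claims about electronic structure; what
matters for learning is that they are consistent and informative.

# Network architecture

For input $X \in \mathbb{R}^{L \times 42}$ the default model is

$$
X \xrightarrow{\text{conv}_1\,(128 \text{ filters},\,k_1{=}7)}
  \xrightarrow{\text{LeakyReLU}}
  \xrightarrow{\text{avgpool}\,(7)}
  \xrightarrow{\text{conv}_2\,(64 \text{ filters},\,k_2{=}7)}
  \xrightarrow{\text{LeakyReLU}}
  \xrightarrow{\text{global max}} \mathbf{f} \in \mathbb{R}^{64}
$$

followed by a dense layer (96 units, LeakyReLU) and a sigmoid output for
binary classification.  $\mathbf{f}$ is the SCFP.  All convolutions and
pooling use stride 1 and no padding by default; both are configurable
(`scfp_model_config()`), and `validate_in_search_space()` checks a
configuration against the documented hyperparameter search space.

Key choices:

* **Global max pooling** ties each fingerprint dimension to a single best
  position in the string, which is what makes motif traceback well-defined.
  Padded positions are masked: only positions whose receptive field starts
  inside the valid rows compete for the maximum, so the fingerprint of a
  compound does not depend on how much padding follows it.
* **LeakyReLU (slope 0.2)** keeps gradients alive on the negative side —
  helpful because the input is sparse and many filter responses start
  negative.
* **Initialization** is $\mathcal{N}(0, 0.01^2)$ for weights, zero for
  biases, fully determined by a seed.
* Optional **batch normalization** after each convolution and **dropout**
  before the output layer are available but off by default.

## Receptive field and the motif-size bound

With stride-1 convolutions ($k_1$, $k_2$) and an average pool of width
$k_1$ between them, one unit of the final map sees at most

$$ 2k_1 + k_2 \;=\; 21 \text{ SMILES symbols (defaults } k_1 = k_2 = 7) $$

`receptive_field_bound()` composes the exact per-layer geometry (19 symbols
at the defaults, which is ≤ the closed-form bound of 21);
`traceback_span()` inverts it, mapping a final-map position to the 1-based
inclusive interval of input rows that can influence it.  Both are verified
in the test suite against a perturbation oracle: inject a large value into
one input row and observe exactly which final-map positions change.

# Training

`train_scfp()` minimizes binary cross-entropy (optionally MSE) by
mini-batch gradient descent with Adam (default, learning rate $0.01$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$) or AdaGrad.  Batches of 32, shuffled
per epoch from the training-config seed; runs are bit-reproducible.  The
backward pass is hand-derived and checked against numeric differentiation
to $10^{-5}$ relative tolerance in the tests (the check perturbs away from
the kink-free region of the activations).  `cross_validate()` provides
stratified $k$-fold evaluation with per-fold ROC-AUC (computed by pROC and
cross-checked against a brute-force pairwise implementation).

# Motif detection

Let $f_j(x)$ be fingerprint dimension $j$ of compound $x$, and let
$\mu_j, \sigma_j$ be its mean and standard deviation over a background
dataset (`fit_filter_stats()`; dimensions with zero variance are flagged
and excluded).  A motif is called when

$$ z_j(x) = \frac{f_j(x) - \mu_j}{\sigma_j} > 2.58, $$

i.e. the response exceeds the upper 0.5% tail of a normal background —
conservative enough that calls concentrate on filters that respond to
specific substructures.  The called filter's argmax position is traced back
with `traceback_span()`, clipped to the valid rows, and reported with the
SMILES substring and the atom ordinals inside the span.

The choice of background matters: statistics should be fit on compounds
that mostly *lack* the structures of interest (in the synthetic benchmark,
the inactives), so that planted structure in actives registers as an
excursion.  In heavily imbalanced screening data the whole dataset is an
acceptable background because actives are rare; with balanced classes, use
the inactives.

# Synthetic planted-motif benchmark

`generate_planted_dataset()` builds a labelled dataset with a known ground
truth so the entire pipeline can be validated without external data:

* Scaffolds are random valence-respecting trees of 8–30 heavy atoms over a
  carbon-dominant alphabet (C 70%, N/O 12% each, S/F/Cl/Br rare), with
  branch probability 0.3, ring-closure probability 0.2 (tree distance 2–6),
  and double-bond probability 0.1.  These defaults roughly mimic the size
  and element distribution of screening libraries; they are study
  conditions, not tuned constants.
* **Actives** get one copy of the planted fragment (default `C(=O)O`)
  attached at a random carbon with free valence; **inactives** are
  rejection-sampled until they contain no copy of the fragment.
* After canonicalization the fragment's atom positions are recomputed by
  subgraph matching (VF2 on element- and bond-order-coloured graphs), so
  ground truth survives atom reordering.  An independent toolkit (RDKit)
  confirms both parseability and fragment presence in the tests.

What the generator does *not* emulate: realistic pharmacophores,
stereochemistry, charged species, tautomers, or activity cliffs.  It tests
the mechanics of learning and localization, not chemical realism.

The default class balance (50 actives : 500 inactives) mirrors the heavy
imbalance of screening assays; the acceptance benchmark uses a balanced
200:200 design so that held-out ROC-AUC is a sensitive readout.

# Baselines and visualization

`ecfp_fingerprints()` computes circular (ECFP4-class) fingerprints via Open
Babel, folded to 1024 bits, and `embed_chemical_space()` projects any
fingerprint matrix to 2-D by classical multidimensional scaling — useful
for comparing the learned space with the ECFP space on the same compounds.

# Numerical notes

* Convolutions are im2col + BLAS matrix products; training a 400-compound
  balanced benchmark for 30 epochs takes on the order of two minutes on a
  single CPU.
* Checkpoints and filter statistics serialize to JSON at full double
  precision (`digits = NA`), so a reloaded model reproduces scores to
  machine precision.
* ROC-AUC uses `pROC` with explicit `direction`/`levels` so that scores
  are always interpreted as "higher = more active".

# Worked example

```{r example, eval = FALSE}
set.seed(1)
d <- generate_planted_dataset(scfp_gen_params(n_active = 50, n_inactive = 50))
fs <- featurize_dataset(d)
model <- build_model(scfp_model_config(), seed = 1)
fit <- train_scfp(model, fs, config = scfp_train_config(epochs = 20))
st <- fit_filter_stats(fit$model, subset_featurized(fs, which(d$label == 0)))
detect_motifs(fit$model, subset_featurized(fs, which(d$label == 1)), st)
```
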