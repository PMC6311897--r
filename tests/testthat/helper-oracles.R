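# Independent oracles used across test files.

# Brute-force pairwise ROC-AUC: P(score_active > score_inactive) + 0.5 ties.
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Cross-toolkit oracle: run a python/rdkit snippet over SMILES written one
# per line; returns stdout lines.
rdkit_run <- function(smiles, py_body) {
  smi_file <- tempfile(fileext = ".smi")
  writeLines(smiles, smi_file)
  script <- tempfile(fileext = ".py")
  writeLines(c("import sys", "from rdkit import Chem",
               sprintf("lines=[l.strip() for l in open(%s)]",
                       deparse(smi_file)),
               py_body), script)
  out <- suppressWarnings(system2("python", script, stdout = TRUE,
                                  stderr = FALSE))
  unlink(c(smi_file, script))
  out
}

# Perturbation-derived influence set: which input rows change any entry of
# the final (pre-global-max) map at position t_out.  One batched forward:
# row 1 = base input, row r+1 = base with input row r shifted by +delta.
# Weights are made positive so the network is monotone increasing in every
# input: a positive perturbation then strictly increases every unit whose
# receptive field contains the row, even through max pooling (a negative
# propagation could otherwise be absorbed by a max and hide true influence).
perturbation_influence <- function(model, L, delta = 1e3, seed = 1) {
  model$W1 <- abs(model$W1)
  model$W2 <- abs(model$W2)
  set.seed(seed)
  x <- array(stats::rnorm(L * 42), dim = c(1, L, 42))
  xs <- array(0, dim = c(L + 1, L, 42))
  xs[1, , ] <- x[1, , ]
  for (r in seq_len(L)) {
    xs[r + 1, , ] <- x[1, , ]
    xs[r + 1, r, ] <- xs[r + 1, r, ] + delta
  }
  fw <- scfp_forward(model, xs, valid_len = rep(L, L + 1), cache = TRUE)
  final <- fw$cache$final                       # (L+1) x Lf x F
  Lf <- dim(final)[2]
  base <- final[1, , , drop = FALSE]
  lapply(seq_len(Lf), function(t) {
    which(vapply(seq_len(L), function(r)
      any(abs(final[r + 1, t, ] - base[1, t, ]) > 1e-9), TRUE))
  })
}

# Small random model config guaranteed to yield >= 1 final-map position at
# input length L.  Strides are kept <= window widths: a layer with stride >
# window skips input rows entirely, so its influence set is not an interval
# and the interval-valued traceback is only an upper bound there.
random_small_config <- function(L) {
  repeat {
    p1w <- sample(1:3, 1)
    cfg <- try(scfp_model_config(
      conv1_filters = sample(2:4, 1), conv1_window = sample(2:5, 1),
      conv1_stride = sample(1:2, 1),
      conv1_padding = sample(c("none", "half"), 1),
      pool1_type = sample(c("average", "max"), 1),
      pool1_window = p1w, pool1_stride = sample(seq_len(min(2, p1w)), 1),
      pool1_padding = "none",
      conv2_filters = sample(2:4, 1), conv2_window = sample(2:5, 1),
      conv2_stride = sample(1:2, 1),
      conv2_padding = sample(c("none", "half"), 1),
      pool2_type = sample(c("average", "max"), 1),
      pool2_window = sample(1:2, 1), pool2_stride = 1,
      pool2_padding = "none"), silent = TRUE)
    if (inherits(cfg, "try-error")) next
    Lf <- L
    for (g in scfp:::layer_geometry(cfg)) Lf <- scfp:::out_len(Lf, g)
    if (Lf >= 1) return(cfg)
  }
}

# shared small labeled dataset for quick training tests
quick_dataset <- local({
  d <- NULL
  function() {
    if (is.null(d))
      d <<- generate_planted_dataset(
        scfp_gen_params(n_active = 15L, n_inactive = 25L,
                        scaffold_atoms = c(6L, 14L), seed = 99L))
    d
  }
})
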