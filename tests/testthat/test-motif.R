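test_that("filter statistics match a two-pass oracle", {
  d <- quick_dataset()
  fs <- featurize_dataset(d)
  model <- build_model(scfp_model_config(conv1_filters = 8L,
                                         conv2_filters = 6L,
                                         hidden_units = 8L), seed = 13L)
  st <- fit_filter_stats(model, fs)
  fp <- scfp_forward(model, fs$x, valid_len = fs$valid_len)$scfp
  for (f in seq_len(ncol(fp))) {
    expect_equal(st$mean[f], sum(fp[, f]) / nrow(fp), tolerance = 1e-12)
    expect_equal(st$sd[f],
                 sqrt(sum((fp[, f] - mean(fp[, f]))^2) / (nrow(fp) - 1)),
                 tolerance = 1e-12)
  }
  expect_identical(st$n, nrow(fp))
  expect_error(fit_filter_stats(model, subset_featurized(fs, 1L)), "2")
})

test_that("z-score normalization centers and scales; zero variance flagged", {
  d <- quick_dataset()
  fs <- featurize_dataset(d)
  model <- build_model(scfp_model_config(conv1_filters = 8L,
                                         conv2_filters = 6L,
                                         hidden_units = 8L), seed = 13L)
  st <- fit_filter_stats(model, fs)
  z <- normalize_scfp(scfp_forward(model, fs$x, valid_len = fs$valid_len)$scfp,
                      st)
  live <- !st$zero_variance
  expect_true(all(abs(colMeans(z[, live, drop = FALSE])) < 1e-10))
  expect_true(all(abs(apply(z[, live, drop = FALSE], 2, sd) - 1) < 1e-10))
  # inject a constant filter via degenerate weights
  model2 <- model
  model2$W2[, 1] <- 0; model2$b2[1] <- 1
  expect_warning(st2 <- fit_filter_stats(model2, fs), "zero variance")
  expect_true(st2$zero_variance[1])
  z2 <- suppressWarnings(normalize_scfp(
    scfp_forward(model2, fs$x, valid_len = fs$valid_len)$scfp, st2))
  expect_true(all(is.na(z2[, 1])))
})

test_that("detected motifs report consistent spans, substrings and atoms", {
  d <- quick_dataset()
  fs <- featurize_dataset(d)
  model <- build_model(scfp_model_config(conv1_filters = 8L,
                                         conv2_filters = 6L,
                                         hidden_units = 8L), seed = 13L)
  st <- fit_filter_stats(model, fs)
  hits <- detect_motifs(model, fs, st, threshold = 1.0)  # low threshold
  expect_s3_class(hits, "scfp_motifs")
  expect_gt(nrow(hits), 0L)
  expect_true(all(hits$z > 1.0))
  bound <- motif_size_bound(model$config)
  for (r in seq_len(nrow(hits))) {
    i <- match(hits$compound_id[r], fs$ids)
    tk <- fs$tokens[[i]]
    expect_gte(hits$span_start[r], 1L)
    expect_lte(hits$span_end[r], fs$valid_len[i])
    expect_lte(hits$span_end[r] - hits$span_start[r] + 1L, bound)
    # substring equals the concatenated token texts of the span
    span_tok <- tk$tokens[hits$span_start[r]:hits$span_end[r], ]
    expect_identical(hits$substring[r],
                     substr(tk$canonical_smiles, span_tok$start[1] + 1L,
                            span_tok$end[nrow(span_tok)]))
    expect_identical(hits$atom_ordinals[[r]],
                     span_tok$atom_ordinal[span_tok$kind == "ATOM"])
  }
  # higher threshold yields a subset
  hits2 <- detect_motifs(model, fs, st, threshold = 2.0)
  expect_lte(nrow(hits2), nrow(hits))
})

test_that("motif report round-trips through TSV", {
  d <- quick_dataset()
  fs <- featurize_dataset(d)
  model <- build_model(scfp_model_config(conv1_filters = 8L,
                                         conv2_filters = 6L,
                                         hidden_units = 8L), seed = 13L)
  st <- fit_filter_stats(model, fs)
  hits <- detect_motifs(model, fs, st, threshold = 1.0)
  path <- tempfile(fileext = ".tsv")
  write_motif_report(hits, path)
  back <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, comment.char = "")
  expect_identical(nrow(back), nrow(hits))
  expect_equal(back$z, hits$z, tolerance = 1e-12)
  expect_identical(back$span_start, hits$span_start)
  expect_identical(
    back$atom_ordinals[1],
    paste(hits$atom_ordinals[[1]], collapse = ";"))
})

test_that("ECFP fingerprints and MDS embedding behave sanely", {
  smi <- c("CCO", "CCCO", "CCCCO", "C1C=CC=CC=1", "CC(=O)O")
  fp <- ecfp_fingerprints(smi)
  expect_identical(dim(fp), c(5L, 1024L))
  expect_true(all(fp %in% c(0L, 1L)))
  # identical molecules share fingerprints; different ones differ
  expect_identical(ecfp_fingerprints(c("CCO", "OCC"))[1, ],
                   ecfp_fingerprints(c("CCO", "OCC"))[2, ])
  expect_false(identical(fp[1, ], fp[4, ]))
  emb <- embed_chemical_space(fp, k = 2L)
  expect_identical(dim(emb), c(5L, 2L))
  expect_error(embed_chemical_space(fp[1:2, , drop = FALSE]), "3")
})
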