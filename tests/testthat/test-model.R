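test_that("default configuration matches the documented architecture", {
  cfg <- scfp_model_config()
  expect_identical(cfg$conv1_filters, 128L)
  expect_identical(cfg$conv1_window, 7L)
  expect_identical(cfg$conv2_filters, 64L)
  expect_identical(cfg$conv2_window, 7L)
  expect_identical(cfg$pool1_type, "average")
  expect_identical(cfg$hidden_units, 96L)
  expect_true(validate_in_search_space(cfg))
  expect_error(scfp_model_config(conv1_filters = 0L), "conv1_filters")
})

test_that("model initialization is seeded N(0, 0.01) with zero biases", {
  m1 <- build_model(scfp_model_config(), seed = 5L)
  m2 <- build_model(scfp_model_config(), seed = 5L)
  m3 <- build_model(scfp_model_config(), seed = 6L)
  expect_identical(m1$W1, m2$W1)
  expect_false(identical(m1$W1, m3$W1))
  expect_true(all(m1$b1 == 0) && all(m1$b2 == 0) && all(m1$bh == 0))
  # sd of many N(0, 0.01) draws
  expect_lt(abs(sd(m1$W1) - 0.01), 0.001)
  expect_lt(abs(mean(m1$W1)), 0.001)
})

test_that("forward pass has correct shapes and masked global max", {
  cfg <- scfp_model_config()
  model <- build_model(cfg, seed = 1L)
  fs <- featurize_dataset(data.frame(id = c("a", "b"),
                                     smiles = c("CCO", "CCCCCCCCCCCCCCCCCCCCCCCCC"),
                                     stringsAsFactors = FALSE))
  fw <- scfp_forward(model, fs$x, valid_len = fs$valid_len, cache = TRUE)
  expect_identical(dim(fw$scfp), c(2L, 64L))
  expect_length(fw$scores, 2L)
  expect_true(all(fw$scores > 0 & fw$scores < 1))
  # masking: short compound's argmax must map back to valid input rows
  for (f in 1:64) {
    sp <- traceback_span(cfg, fw$argmax[1, f], valid_len = fs$valid_len[1])
    expect_lte(sp["start"], fs$valid_len[1])
  }
  # padding invariance: extending the pad must not change a masked SCFP
  cfg_small <- featurizer_config(max_len = 40L)
  cfg_big <- featurizer_config(max_len = 60L)
  fa <- featurize_smiles("CCO", cfg_small)
  fb <- featurize_smiles("CCO", cfg_big)
  sa <- compute_scfp(model, fa)
  sb <- compute_scfp(model, fb)
  expect_equal(sa, sb, tolerance = 1e-12)
})

test_that("receptive field bound composes layer geometry exactly", {
  cfg <- scfp_model_config()
  expect_identical(receptive_field_bound(cfg), 19L)
  expect_identical(motif_size_bound(cfg), 21L)
  expect_identical(motif_size_bound(k1 = 11L, k2 = 5L), 27L)
  # per-layer composition oracle: r <- r + (k-1)*jump for stride-1 layers
  expect_identical(receptive_field_bound(scfp_model_config(
    conv1_window = 3L, pool1_window = 1L, conv2_window = 3L,
    pool2_window = 1L)), 5L)
  # traceback of position 1 at defaults starts at input row 1
  expect_identical(traceback_span(cfg, 1L), c(start = 1L, end = 19L))
  expect_identical(traceback_span(cfg, 3L), c(start = 3L, end = 21L))
  expect_error(traceback_span(cfg, 0L), "position")
  # input_len validates against the true final-map length and clips
  expect_identical(traceback_span(cfg, 12L, input_len = 30L),
                   c(start = 12L, end = 30L))
  expect_error(traceback_span(cfg, 3L, input_len = 20L), "out of range")
  # valid_len clips reported rows and rejects inadmissible positions
  expect_identical(traceback_span(cfg, 3L, valid_len = 20L),
                   c(start = 3L, end = 20L))
  expect_error(traceback_span(cfg, 25L, valid_len = 20L), "valid_len")
})

test_that("perturbation influence equals traceback_span at the default config", {
  L <- 30L
  model <- build_model(scfp_model_config(), seed = 2L)
  infl <- perturbation_influence(model, L, seed = 2)
  for (t in seq_along(infl)) {
    sp <- traceback_span(model$config, t)
    expect_identical(infl[[t]], seq.int(max(1L, sp["start"]),
                                        min(L, sp["end"])))
  }
})

test_that("analytic gradients match numeric differentiation", {
  cfg <- scfp_model_config(conv1_filters = 4L, conv1_window = 3L,
                           pool1_window = 2L, conv2_filters = 3L,
                           conv2_window = 3L, hidden_units = 5L)
  model <- build_model(cfg, seed = 3L)
  # scale weights away from the kink-prone near-zero init so the loss is
  # locally smooth around the evaluation point
  for (w in c("W1", "W2", "Wh", "Wo"))
    model[[w]] <- model[[w]] * 50
  set.seed(4)
  L <- 15L
  x <- array(rnorm(2 * L * 42), dim = c(2, L, 42))
  y <- c(1, 0)
  loss_of <- function(m) {
    fw <- scfp_forward(m, x, valid_len = c(L, L))
    p <- pmin(pmax(fw$scores, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- scfp_forward(model, x, valid_len = c(L, L), cache = TRUE)
  gr <- scfp:::scfp_backward(model, fw, y, loss = "cross_entropy",
                             pos_weight = 1)$grads
  eps <- 1e-6
  for (w in c("W1", "b1", "W2", "b2", "Wh", "bh", "Wo", "bo")) {
    param <- model[[w]]
    idx <- if (length(param) > 6) sample(seq_along(param), 6) else seq_along(param)
    for (j in idx) {
      mp <- model; mp[[w]][j] <- mp[[w]][j] + eps
      mm <- model; mm[[w]][j] <- mm[[w]][j] - eps
      num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(as.numeric(gr[[w]][j]), num, tolerance = 1e-5)
    }
  }
})

test_that("model checkpoints round-trip through JSON", {
  model <- build_model(scfp_model_config(conv1_filters = 3L,
                                         conv2_filters = 2L,
                                         hidden_units = 4L), seed = 9L)
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  for (w in c("W1", "b1", "W2", "b2", "Wh", "bh", "Wo", "bo"))
    expect_equal(back[[w]], model[[w]], tolerance = 1e-14)
  expect_identical(back$config, model$config)
  # forward passes agree bit for bit on the same input
  x <- array(rnorm(1 * 25 * 42), dim = c(1, 25, 42))
  expect_equal(scfp_forward(back, x)$scores, scfp_forward(model, x)$scores,
               tolerance = 1e-14)
  expect_error(suppressWarnings(load_model(tempfile())), ".")
})
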