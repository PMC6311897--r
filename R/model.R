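# Two-stage 1-D convolutional network -----------------------------------------
#
# Architecture: a first convolution spanning the full 42-column width of the
# feature matrix (so convolution runs only along the SMILES string), an
# average/max pooling stage, a second convolution, an optional second pooling
# stage, global max pooling producing the 64-dimensional SCFP, then one fully
# connected hidden layer and a sigmoid output unit.

#' Model configuration
#'
#' Defaults fix both convolution windows at 7 with stride 1 and the first
#' pooling window equal to the first convolution window, so the maximum
#' detectable motif size is the bound 2*k1 + k2 = 21 SMILES symbols and the
#' exact receptive span of a second-convolution unit is 19.  The second
#' convolution has 64 filters: the global-max-pooled output (the SCFP) is
#' 64-dimensional.  All settings from the architecture search space (windows
#' in \[1, 51\], strides in \{1, 3, 5\}, pooling type, padding policy,
#' activation, batch normalization, dropout) remain configurable.
#'
#' @param conv1_filters,conv1_window,conv1_stride,conv1_padding first
#'   convolution: filter count, window size k1, stride, padding policy
#'   (`"none"` or `"half"`).
#' @param pool1_type,pool1_window,pool1_stride,pool1_padding first pooling
#'   stage (`"average"` or `"max"`).
#' @param conv2_filters,conv2_window,conv2_stride,conv2_padding second
#'   convolution; `conv2_filters` is the SCFP dimension.
#' @param pool2_type,pool2_window,pool2_stride,pool2_padding second pooling
#'   stage; window 1 (the default) is the identity.
#' @param hidden_units fully connected hidden layer width.
#' @param activation `"leaky_relu"` (default), `"relu"` or `"prelu"`-style
#'   fixed slope via `leaky_slope`.
#' @param leaky_slope negative-branch slope of the leaky activation.
#' @param batch_norm apply batch normalization after each convolution.
#' @param dropout dropout probability on the hidden layer (0 disables).
#' @param mask_padding exclude final-map positions whose receptive field lies
#'   entirely in zero padding from the global max.
#' @return validated `scfp_model_config` object.
#' @export
scfp_model_config <- function(conv1_filters = 128L, conv1_window = 7L,
                              conv1_stride = 1L, conv1_padding = "none",
                              pool1_type = "average", pool1_window = conv1_window,
                              pool1_stride = 1L, pool1_padding = "none",
                              conv2_filters = 64L, conv2_window = 7L,
                              conv2_stride = 1L, conv2_padding = "none",
                              pool2_type = "average", pool2_window = 1L,
                              pool2_stride = 1L, pool2_padding = "none",
                              hidden_units = 96L,
                              activation = c("leaky_relu", "relu"),
                              leaky_slope = 0.2,
                              batch_norm = FALSE, dropout = 0,
                              mask_padding = TRUE) {
  activation <- match.arg(activation)
  cfg <- list(conv1_filters = as.integer(conv1_filters),
              conv1_window = as.integer(conv1_window),
              conv1_stride = as.integer(conv1_stride),
              conv1_padding = conv1_padding,
              pool1_type = pool1_type,
              pool1_window = as.integer(pool1_window),
              pool1_stride = as.integer(pool1_stride),
              pool1_padding = pool1_padding,
              conv2_filters = as.integer(conv2_filters),
              conv2_window = as.integer(conv2_window),
              conv2_stride = as.integer(conv2_stride),
              conv2_padding = conv2_padding,
              pool2_type = pool2_type,
              pool2_window = as.integer(pool2_window),
              pool2_stride = as.integer(pool2_stride),
              pool2_padding = pool2_padding,
              hidden_units = as.integer(hidden_units),
              activation = activation,
              leaky_slope = as.numeric(leaky_slope),
              batch_norm = isTRUE(batch_norm),
              dropout = as.numeric(dropout),
              mask_padding = isTRUE(mask_padding))
  problems <- character(0)
  for (f in c("conv1_filters", "conv1_window", "conv1_stride", "pool1_window",
              "pool1_stride", "conv2_filters", "conv2_window", "conv2_stride",
              "pool2_window", "pool2_stride", "hidden_units")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) problems <- c(problems, f)
  }
  for (f in c("pool1_type", "pool2_type"))
    if (!cfg[[f]] %in% c("average", "max")) problems <- c(problems, f)
  for (f in c("conv1_padding", "conv2_padding", "pool1_padding", "pool2_padding"))
    if (!cfg[[f]] %in% c("none", "half")) problems <- c(problems, f)
  if (!is.numeric(cfg$dropout) || cfg$dropout < 0 || cfg$dropout >= 1)
    problems <- c(problems, "dropout")
  if (length(problems))
    stop("invalid model configuration field(s): ",
         paste(problems, collapse = ", "), call. = FALSE)
  structure(cfg, class = "scfp_model_config")
}

#' Architecture search space (for reference/validation)
#'
#' The hyperparameter ranges explored in the original architecture search:
#' windows in \[1, 51\], filter counts in \[1, 1024\], strides in
#' \{1, 3, 5\}, both pooling types, optional half-window padding.
#'
#' @return a list of ranges.
#' @export
scfp_search_space <- function() {
  list(filters = c(1L, 1024L), window = c(1L, 51L), stride = c(1L, 3L, 5L),
       pool_type = c("max", "average"), padding = c("none", "half"),
       minibatch = c(32L, 64L, 128L, 256L, 512L),
       learning_rate = c(1e-4, 1e-3, 1e-2, 1e-1),
       optimizer = c("adam", "adagrad"),
       activation = c("relu", "leaky_relu"),
       loss = c("cross_entropy", "mse"))
}

#' Check a model configuration against the search space
#'
#' @param config a [scfp_model_config()].
#' @return `TRUE` invisibly, or an error listing out-of-range fields.
#' @export
validate_in_search_space <- function(config) {
  ss <- scfp_search_space()
  bad <- character(0)
  for (f in c("conv1_window", "conv2_window", "pool1_window", "pool2_window"))
    if (config[[f]] < ss$window[1] || config[[f]] > ss$window[2])
      bad <- c(bad, f)
  for (f in c("conv1_filters", "conv2_filters"))
    if (config[[f]] < ss$filters[1] || config[[f]] > ss$filters[2])
      bad <- c(bad, f)
  for (f in c("conv1_stride", "conv2_stride", "pool1_stride", "pool2_stride"))
    if (!config[[f]] %in% ss$stride) bad <- c(bad, f)
  if (length(bad))
    stop("configuration outside the search space: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# The four sequence-direction layers as (window, stride, left padding).
layer_geometry <- function(config) {
  pad <- function(policy, k) if (policy == "half") k %/% 2L else 0L
  list(
    conv1 = list(k = config$conv1_window, s = config$conv1_stride,
                 p = pad(config$conv1_padding, config$conv1_window)),
    pool1 = list(k = config$pool1_window, s = config$pool1_stride,
                 p = pad(config$pool1_padding, config$pool1_window)),
    conv2 = list(k = config$conv2_window, s = config$conv2_stride,
                 p = pad(config$conv2_padding, config$conv2_window)),
    pool2 = list(k = config$pool2_window, s = config$pool2_stride,
                 p = pad(config$pool2_padding, config$pool2_window)))
}

out_len <- function(L, g) {
  n <- (L + 2L * g$p - g$k) %/% g$s + 1L
  if (n < 1L) stop("layer output length < 1 (input too short for window ",
                   g$k, ")", call. = FALSE)
  n
}

#' Exact receptive-field width of one final-map unit
#'
#' The number of input rows that can influence a single unit of the map that
#' feeds global max pooling, computed from the configured windows and
#' strides.  At the defaults this is 19, below the motif-size bound
#' [motif_size_bound()] of 2*k1 + k2 = 21.
#'
#' @param config a [scfp_model_config()].
#' @return integer width in SMILES symbols.
#' @export
receptive_field_bound <- function(config) {
  r <- 1L; j <- 1L
  for (g in layer_geometry(config)) {
    r <- r + (g$k - 1L) * j
    j <- j * g$s
  }
  r
}

#' Maximum detectable motif size (window-size bound)
#'
#' The closed-form bound on the size of a detectable chemical motif in SMILES
#' symbols, `2*k1 + k2`, where `k1` and `k2` are the first and second
#' convolution window sizes.  With the default windows (7 and 7) the bound is
#' 21.  [receptive_field_bound()] gives the exact span, which equals this
#' bound when the first pooling window equals `k1` and all strides are 1 and
#' is smaller otherwise.
#'
#' @param config a [scfp_model_config()], or `NULL` to pass windows directly.
#' @param k1,k2 convolution window sizes (ignored when `config` is given).
#' @return integer bound in SMILES symbols.
#' @export
motif_size_bound <- function(config = NULL, k1 = 7L, k2 = 7L) {
  if (!is.null(config)) {
    k1 <- config$conv1_window
    k2 <- config$conv2_window
  }
  2L * as.integer(k1) + as.integer(k2)
}

#' Input rows influencing one final-map position
#'
#' Traces a position of the map feeding global max pooling back through
#' pool2, conv2, pool1 and conv1 to the interval of input rows that can
#' influence it.  Rows are 1-based inclusive.
#'
#' Without `input_len` the theoretical interval is returned (it may extend
#' beyond the input, or below row 1 for padded configurations).  With
#' `input_len` — the row count of the array the network actually ran on —
#' the interval is clipped against each intermediate map's true length, so
#' it is exact for strided and padded configurations too.
#'
#' The interval is exact whenever every layer has stride <= window width.
#' A layer with stride > window skips input rows, so the true influence set
#' has gaps; the returned interval is then an upper bound (the influence
#' cone).
#'
#' @param config a [scfp_model_config()].
#' @param position 1-based position in the final map.
#' @param input_len row count of the network input; validates the position
#'   and clips the interval per layer.
#' @param valid_len number of non-padding rows; errors if the interval
#'   starts past it (an inadmissible position under padding masking) and
#'   clips the end to it.
#' @return integer vector `c(start, end)`, 1-based inclusive input rows.
#' @export
traceback_span <- function(config, position, input_len = NULL,
                           valid_len = NULL) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("position must be a positive integer", call. = FALSE)
  geom <- layer_geometry(config)
  lens <- NULL
  if (!is.null(input_len)) {
    lens <- as.integer(input_len)              # per-layer input lengths
    for (g in geom) lens <- c(lens, out_len(lens[length(lens)], g))
    if (position > lens[length(lens)])
      stop("position ", position, " out of range (final map has ",
           lens[length(lens)], " positions)", call. = FALSE)
  }
  a <- position; b <- position
  for (i in rev(seq_along(geom))) {
    g <- geom[[i]]
    if (!is.null(lens)) {
      a <- max(a, 1L)
      b <- min(b, lens[i + 1L])
    }
    a <- (a - 1L) * g$s + 1L - g$p
    b <- (b - 1L) * g$s + 1L - g$p + g$k - 1L
  }
  if (!is.null(lens)) {
    a <- max(a, 1L)
    b <- min(b, lens[1L])
  }
  if (!is.null(valid_len)) {
    if (a > as.integer(valid_len))
      stop("position ", position, " maps to input rows past valid_len = ",
           valid_len, call. = FALSE)
    a <- max(a, 1L)
    b <- min(b, as.integer(valid_len))
  }
  c(start = a, end = b)
}

#' Build a model with freshly initialized weights
#'
#' All weights are drawn from N(0, 0.01^2) with the given seed; biases start
#' at zero.  The same seed reproduces the same weights bit for bit.
#'
#' @param config a [scfp_model_config()].
#' @param seed integer RNG seed.
#' @return an `scfp_model` object.
#' @export
build_model <- function(config = scfp_model_config(), seed = 1L) {
  stopifnot(inherits(config, "scfp_model_config"))
  set.seed(seed)
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 0.01), nr, nc)
  f1 <- config$conv1_filters; f2 <- config$conv2_filters
  k1 <- config$conv1_window; k2 <- config$conv2_window
  model <- list(
    config = config,
    W1 = rn(k1 * 42L, f1), b1 = numeric(f1),
    W2 = rn(k2 * f1, f2), b2 = numeric(f2),
    Wh = rn(f2, config$hidden_units), bh = numeric(config$hidden_units),
    Wo = rn(config$hidden_units, 1L), bo = 0,
    trained = FALSE)
  if (config$batch_norm) {
    model$bn1 <- list(gamma = rep(1, f1), beta = numeric(f1),
                      mean = numeric(f1), var = rep(1, f1))
    model$bn2 <- list(gamma = rep(1, f2), beta = numeric(f2),
                      mean = numeric(f2), var = rep(1, f2))
  }
  structure(model, class = "scfp_model")
}

# -- array plumbing -----------------------------------------------------------

# Gather sliding windows: x [B, L, C] -> list(cols = (B*Lout) x (k*C), Lout).
# Row (b, t) has b fastest; column (kk, c) has kk fastest.
gather_windows <- function(x, g) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  if (g$p > 0L) {
    xp <- array(0, c(B, L + 2L * g$p, C))
    xp[, g$p + seq_len(L), ] <- x
    x <- xp; L <- L + 2L * g$p
  }
  Lout <- (L - g$k) %/% g$s + 1L
  idx <- outer(seq_len(g$k), (seq_len(Lout) - 1L) * g$s, `+`)  # k x Lout
  xg <- x[, as.vector(idx), , drop = FALSE]                    # B x k*Lout x C
  dim(xg) <- c(B, g$k, Lout, C)
  xg <- aperm(xg, c(1, 3, 2, 4))                               # B x Lout x k x C
  dim(xg) <- c(B * Lout, g$k * C)
  list(cols = xg, Lout = Lout, Lin = L, B = B, C = C)
}

# Scatter-add the gradient of gather_windows back to x shape [B, L, C].
scatter_windows <- function(dcols, g, B, Lout, C, L_orig) {
  Lp <- L_orig + 2L * g$p
  dim(dcols) <- c(B, Lout, g$k, C)
  dx <- array(0, c(B, Lp, C))
  for (kk in seq_len(g$k)) {
    pos <- (seq_len(Lout) - 1L) * g$s + kk
    dx[, pos, ] <- dx[, pos, ] + dcols[, , kk, ]
  }
  if (g$p > 0L) dx <- dx[, g$p + seq_len(L_orig), , drop = FALSE]
  dx
}

pool_forward <- function(x, g, type) {
  gw <- gather_windows(x, g)
  xg <- gw$cols
  dim(xg) <- c(gw$B * gw$Lout, g$k, gw$C)
  if (type == "average") {
    y <- xg[, 1L, ]
    if (!is.matrix(y)) y <- matrix(y, ncol = gw$C)
    if (g$k > 1L) for (kk in 2:g$k) y <- y + xg[, kk, ]
    y <- y / g$k
    arg <- NULL
  } else {
    y <- xg[, 1L, ]
    if (!is.matrix(y)) y <- matrix(y, ncol = gw$C)
    arg <- matrix(1L, nrow(y), ncol(y))
    if (g$k > 1L) for (kk in 2:g$k) {
      cur <- xg[, kk, ]
      if (!is.matrix(cur)) cur <- matrix(cur, ncol = gw$C)
      upd <- cur > y
      y[upd] <- cur[upd]
      arg[upd] <- kk
    }
  }
  yy <- y
  dim(yy) <- c(gw$B, gw$Lout, gw$C)
  list(y = yy, arg = arg, gw = gw)
}

pool_backward <- function(dy, pf, g, type, L_orig) {
  gw <- pf$gw
  dim(dy) <- c(gw$B * gw$Lout, gw$C)
  dcols <- matrix(0, gw$B * gw$Lout, g$k * gw$C)
  dim(dcols) <- c(gw$B * gw$Lout, g$k, gw$C)
  if (type == "average") {
    for (kk in seq_len(g$k)) dcols[, kk, ] <- dy / g$k
  } else {
    for (kk in seq_len(g$k)) dcols[, kk, ] <- dy * (pf$arg == kk)
  }
  dim(dcols) <- c(gw$B * gw$Lout, g$k * gw$C)
  scatter_windows(dcols, g, gw$B, gw$Lout, gw$C, L_orig)
}

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_grad <- function(x, slope) ifelse(x > 0, 1, slope)

sigmoid <- function(x) 1 / (1 + exp(-x))

# -- forward pass -------------------------------------------------------------

as_input_array <- function(x) {
  if (inherits(x, "scfp_matrix")) {
    vl <- attr(x, "valid_len")
    x <- array(unclass(x), dim = c(1L, nrow(x), ncol(x)))
    attr(x, "valid_len") <- vl
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

#' Forward pass: SCFP and classification scores
#'
#' Runs a batch of feature matrices through the network.  The SCFP of a
#' compound is the global max over (non-padding) positions of each
#' second-stage filter's activation map; the score is the sigmoid output of
#' the classification head.
#'
#' @param model an `scfp_model`.
#' @param x either one `scfp_matrix` or a 3-d array `B x max_len x 42` (e.g.
#'   `featurize_dataset()$x`).
#' @param valid_len integer vector of valid (non-padding) row counts, needed
#'   for padding masking when `x` is a plain array.
#' @param cache keep intermediates (for training/backprop and motif
#'   traceback).
#' @param training use batch statistics for batch norm and sample dropout.
#' @return list with `scores` (length B), `scfp` (B x conv2_filters matrix),
#'   `argmax` (B x conv2_filters final-map positions of each SCFP element)
#'   and, if `cache`, the layer intermediates.
#' @export
scfp_forward <- function(model, x, valid_len = NULL, cache = FALSE,
                         training = FALSE) {
  x <- as_input_array(x)
  if (is.null(valid_len)) {
    valid_len <- attr(x, "valid_len")
    if (is.null(valid_len)) valid_len <- rep(dim(x)[2], dim(x)[1])
  }
  cfg <- model$config
  if (dim(x)[3] != 42L)
    stop("input must have 42 feature columns, got ", dim(x)[3], call. = FALSE)
  if (dim(x)[1] != length(valid_len))
    stop("valid_len length does not match batch size", call. = FALSE)
  geom <- layer_geometry(cfg)
  B <- dim(x)[1]; L0 <- dim(x)[2]

  # conv1
  gw1 <- gather_windows(x, geom$conv1)
  z1 <- sweep(gw1$cols %*% model$W1, 2L, model$b1, `+`)
  bn1 <- NULL
  if (cfg$batch_norm) {
    bn1 <- bn_forward(z1, model$bn1, training)
    z1 <- bn1$y
  }
  a1 <- leaky(z1, cfg$leaky_slope)
  a1a <- a1; dim(a1a) <- c(B, gw1$Lout, cfg$conv1_filters)

  # pool1
  pf1 <- pool_forward(a1a, geom$pool1, cfg$pool1_type)

  # conv2
  gw2 <- gather_windows(pf1$y, geom$conv2)
  z2 <- sweep(gw2$cols %*% model$W2, 2L, model$b2, `+`)
  bn2 <- NULL
  if (cfg$batch_norm) {
    bn2 <- bn_forward(z2, model$bn2, training)
    z2 <- bn2$y
  }
  a2 <- leaky(z2, cfg$leaky_slope)
  a2a <- a2; dim(a2a) <- c(B, gw2$Lout, cfg$conv2_filters)

  # pool2 (identity at the default window 1)
  pf2 <- pool_forward(a2a, geom$pool2, cfg$pool2_type)
  final <- pf2$y                      # B x Lf x F2
  Lf <- dim(final)[2]

  # global max over positions whose receptive field touches valid rows
  span_start <- vapply(seq_len(Lf), function(t)
    traceback_span(cfg, t)[["start"]], 1L)
  scfp <- matrix(-Inf, B, cfg$conv2_filters)
  argm <- matrix(1L, B, cfg$conv2_filters)
  for (b in seq_len(B)) {
    ok <- if (cfg$mask_padding) which(span_start <= valid_len[b]) else seq_len(Lf)
    if (!length(ok)) ok <- 1L
    sub <- final[b, ok, , drop = FALSE]
    dim(sub) <- c(length(ok), cfg$conv2_filters)
    am <- max.col(t(sub), ties.method = "first")
    scfp[b, ] <- sub[cbind(am, seq_len(cfg$conv2_filters))]
    argm[b, ] <- ok[am]
  }

  # head
  zh <- sweep(scfp %*% model$Wh, 2L, model$bh, `+`)
  ah <- leaky(zh, cfg$leaky_slope)
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    drop_mask <- matrix(stats::rbinom(length(ah), 1L, 1 - cfg$dropout),
                        nrow(ah), ncol(ah)) / (1 - cfg$dropout)
    ah <- ah * drop_mask
  }
  zo <- drop(ah %*% model$Wo) + model$bo
  scores <- sigmoid(zo)

  out <- list(scores = scores, scfp = scfp, argmax = argm,
              valid_len = valid_len)
  if (cache) {
    out$cache <- list(x = x, gw1 = gw1, z1 = z1, bn1 = bn1, a1a = a1a,
                      pf1 = pf1, gw2 = gw2, z2 = z2, bn2 = bn2, a2a = a2a,
                      pf2 = pf2, final = final, zh = zh, ah = ah,
                      drop_mask = drop_mask, zo = zo, geom = geom,
                      L0 = L0, B = B)
  }
  out
}

#' Compute the SMILES convolution fingerprint of a compound
#'
#' Convenience wrapper: featurize (if given a SMILES string) and run the
#' forward pass; the SCFP can be computed for any compound, not only those in
#' the training data.
#'
#' @param model an `scfp_model`.
#' @param x a SMILES string, an `scfp_matrix`, a 3-d input array, or a
#'   featurized dataset from [featurize_dataset()].
#' @param config featurizer configuration used when `x` is a SMILES string.
#' @return for a single compound, the named numeric SCFP vector (length
#'   `conv2_filters`); for a batch, the matrix of SCFPs (compounds in rows,
#'   with ids as row names when available).
#' @export
compute_scfp <- function(model, x, config = featurizer_config()) {
  if (is.character(x)) x <- featurize_smiles(x, config)
  if (is.list(x) && !is.null(x$x)) {
    fw <- scfp_forward(model, x$x, valid_len = x$valid_len)
    rownames(fw$scfp) <- x$ids
  } else {
    fw <- scfp_forward(model, x)
  }
  if (nrow(fw$scfp) == 1L) drop(fw$scfp) else fw$scfp
}

#' @export
print.scfp_model <- function(x, ...) {
  cfg <- x$config
  cat("SCFP convolutional model (",
      if (isTRUE(x$trained)) "trained" else "untrained", ")\n",
      " conv1: ", cfg$conv1_filters, " filters, window ", cfg$conv1_window,
      "; pool1: ", cfg$pool1_type, " ", cfg$pool1_window, "\n",
      " conv2: ", cfg$conv2_filters, " filters (SCFP dimension), window ",
      cfg$conv2_window, "\n",
      " receptive span ", receptive_field_bound(cfg),
      " (bound 2k1+k2 = ", motif_size_bound(cfg), ")\n", sep = "")
  invisible(x)
}

# batch normalization over rows, per column
bn_forward <- function(z, bn, training, eps = 1e-5, momentum = 0.9) {
  if (training) {
    mu <- colMeans(z)
    v <- colMeans(sweep(z, 2L, mu)^2)
  } else {
    mu <- bn$mean; v <- bn$var
  }
  xhat <- sweep(sweep(z, 2L, mu), 2L, sqrt(v + eps), `/`)
  y <- sweep(sweep(xhat, 2L, bn$gamma, `*`), 2L, bn$beta, `+`)
  list(y = y, xhat = xhat, mu = mu, v = v, eps = eps,
       new_mean = momentum * bn$mean + (1 - momentum) * mu,
       new_var = momentum * bn$var + (1 - momentum) * v)
}

bn_backward <- function(dy, fwd, bn) {
  n <- nrow(dy)
  dgamma <- colSums(dy * fwd$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, bn$gamma, `*`)
  inv <- 1 / sqrt(fwd$v + fwd$eps)
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                sweep(fwd$xhat, 2L, colMeans(dxhat * fwd$xhat), `*`),
              2L, inv, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON format containing the configuration and all weights at
#' full precision.
#'
#' @param model an `scfp_model`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "scfp_model"))
  ser <- list(
    format = "scfp-checkpoint-v1",
    config = unclass(model$config),
    weights = list(
      W1 = list(dim = dim(model$W1), data = as.numeric(model$W1)),
      b1 = model$b1,
      W2 = list(dim = dim(model$W2), data = as.numeric(model$W2)),
      b2 = model$b2,
      Wh = list(dim = dim(model$Wh), data = as.numeric(model$Wh)),
      bh = model$bh,
      Wo = list(dim = dim(model$Wo), data = as.numeric(model$Wo)),
      bo = model$bo),
    bn1 = model$bn1, bn2 = model$bn2,
    trained = isTRUE(model$trained))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(ser$format, "scfp-checkpoint-v1"))
    stop("not an scfp checkpoint: ", path, call. = FALSE)
  cfg <- do.call(scfp_model_config, ser$config[
    setdiff(names(ser$config), character(0))])
  unmat <- function(w) matrix(w$data, w$dim[1], w$dim[2])
  model <- list(config = cfg,
                W1 = unmat(ser$weights$W1), b1 = as.numeric(ser$weights$b1),
                W2 = unmat(ser$weights$W2), b2 = as.numeric(ser$weights$b2),
                Wh = unmat(ser$weights$Wh), bh = as.numeric(ser$weights$bh),
                Wo = unmat(ser$weights$Wo), bo = as.numeric(ser$weights$bo),
                trained = isTRUE(ser$trained))
  if (!is.null(ser$bn1)) { model$bn1 <- ser$bn1; model$bn2 <- ser$bn2 }
  structure(model, class = "scfp_model")
}
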