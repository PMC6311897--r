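# Training: mini-batch SGD with Adam/AdaGrad, ROC-AUC evaluation, and
# stratified k-fold cross validation.

#' Training configuration
#'
#' @param optimizer `"adam"` (default) or `"adagrad"`.
#' @param learning_rate step size; default 0.01.
#' @param minibatch_size mini-batch size; default 32.
#' @param loss `"cross_entropy"` (default) or `"mse"`.
#' @param epochs number of passes over the training data; default 20 (the
#'   validation ROC-AUC typically converges by then).
#' @param seed RNG seed controlling shuffling (and dropout, if enabled).
#' @param patience optional early-stopping patience: stop when the validation
#'   ROC-AUC has not improved for this many epochs (`NULL` disables).
#' @param pos_weight multiplier on the loss gradient of positive examples
#'   (class-imbalance handling; 1 = off, the default).
#' @return validated `scfp_train_config`.
#' @export
scfp_train_config <- function(optimizer = c("adam", "adagrad"),
                              learning_rate = 0.01, minibatch_size = 32L,
                              loss = c("cross_entropy", "mse"),
                              epochs = 20L, seed = 1L, patience = NULL,
                              pos_weight = 1) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("learning_rate must be > 0", call. = FALSE)
  minibatch_size <- as.integer(minibatch_size)
  if (is.na(minibatch_size) || minibatch_size < 1L)
    stop("minibatch_size must be >= 1", call. = FALSE)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 minibatch_size = minibatch_size, loss = loss,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 patience = patience, pos_weight = pos_weight),
            class = "scfp_train_config")
}

# gradients of all parameters given a cached forward pass
scfp_backward <- function(model, fw, y, loss = "cross_entropy",
                          pos_weight = 1) {
  cfg <- model$config
  ca <- fw$cache
  B <- ca$B
  p <- fw$scores
  eps <- 1e-12
  w <- ifelse(y == 1, pos_weight, 1)
  if (loss == "cross_entropy") {
    lossval <- -mean(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps)))
    dzo <- w * (p - y) / B
  } else {
    lossval <- mean(w * (p - y)^2)
    dzo <- 2 * w * (p - y) * p * (1 - p) / B
  }
  dzo <- matrix(dzo, ncol = 1L)

  grads <- list()
  grads$Wo <- crossprod(ca$ah, dzo)
  grads$bo <- sum(dzo)
  dah <- dzo %*% t(model$Wo)
  if (!is.null(ca$drop_mask)) dah <- dah * ca$drop_mask
  dzh <- dah * leaky_grad(ca$zh, cfg$leaky_slope)
  grads$Wh <- crossprod(fw$scfp, dzh)
  grads$bh <- colSums(dzh)
  dscfp <- dzh %*% t(model$Wh)

  # global max: route each SCFP gradient to its argmax final-map position
  dfinal <- array(0, dim(ca$final))
  f2 <- cfg$conv2_filters
  idx3 <- cbind(rep(seq_len(B), times = f2), as.vector(fw$argmax),
                rep(seq_len(f2), each = B))
  dfinal[idx3] <- as.vector(dscfp)

  geom <- ca$geom
  da2a <- pool_backward(dfinal, ca$pf2, geom$pool2, cfg$pool2_type,
                        dim(ca$a2a)[2])
  dz2 <- da2a; dim(dz2) <- c(B * dim(ca$a2a)[2], f2)
  dz2 <- dz2 * leaky_grad(ca$z2, cfg$leaky_slope)
  if (cfg$batch_norm) {
    bb <- bn_backward(dz2, ca$bn2, model$bn2)
    grads$bn2_gamma <- bb$dgamma; grads$bn2_beta <- bb$dbeta
    dz2 <- bb$dx
  }
  grads$W2 <- crossprod(ca$gw2$cols, dz2)
  grads$b2 <- colSums(dz2)
  dcols2 <- dz2 %*% t(model$W2)
  dp1 <- scatter_windows(dcols2, geom$conv2, B, ca$gw2$Lout,
                         cfg$conv1_filters, dim(ca$pf1$y)[2])

  da1a <- pool_backward(dp1, ca$pf1, geom$pool1, cfg$pool1_type,
                        dim(ca$a1a)[2])
  dz1 <- da1a; dim(dz1) <- c(B * dim(ca$a1a)[2], cfg$conv1_filters)
  dz1 <- dz1 * leaky_grad(ca$z1, cfg$leaky_slope)
  if (cfg$batch_norm) {
    bb <- bn_backward(dz1, ca$bn1, model$bn1)
    grads$bn1_gamma <- bb$dgamma; grads$bn1_beta <- bb$dbeta
    dz1 <- bb$dx
  }
  grads$W1 <- crossprod(ca$gw1$cols, dz1)
  grads$b1 <- colSums(dz1)

  list(grads = grads, loss = lossval)
}

make_optimizer <- function(kind, lr) {
  state <- list()
  t <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- function(params, grads) {
    t <<- t + 1L
    for (nm in names(grads)) {
      g <- grads[[nm]]
      if (is.null(state[[nm]])) {
        state[[nm]] <<- list(m = g * 0, v = g * 0)
      }
      s <- state[[nm]]
      if (kind == "adam") {
        s$m <- b1 * s$m + (1 - b1) * g
        s$v <- b2 * s$v + (1 - b2) * g^2
        mhat <- s$m / (1 - b1^t)
        vhat <- s$v / (1 - b2^t)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      } else {  # adagrad
        s$v <- s$v + g^2
        params[[nm]] <- params[[nm]] - lr * g / (sqrt(s$v) + eps)
      }
      state[[nm]] <<- s
    }
    params
  }
  step
}

apply_grad_step <- function(model, grads, stepper) {
  flat <- list(W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
               Wh = model$Wh, bh = model$bh, Wo = model$Wo, bo = model$bo)
  gsub <- grads[names(grads) %in% names(flat)]
  flat <- stepper(flat, gsub)
  model[names(flat)] <- flat
  if (model$config$batch_norm) {
    bn <- list(bn1_gamma = model$bn1$gamma, bn1_beta = model$bn1$beta,
               bn2_gamma = model$bn2$gamma, bn2_beta = model$bn2$beta)
    gbn <- grads[names(grads) %in% names(bn)]
    if (length(gbn)) {
      bn <- stepper(bn, gbn)
      model$bn1$gamma <- bn$bn1_gamma; model$bn1$beta <- bn$bn1_beta
      model$bn2$gamma <- bn$bn2_gamma; model$bn2$beta <- bn$bn2_beta
    }
  }
  model
}

#' Subset a featurized dataset
#'
#' @param fs a [featurize_dataset()] result.
#' @param idx integer or logical compound index.
#' @return the subsetted featurized dataset (same structure).
#' @export
subset_featurized <- function(fs, idx) {
  list(x = fs$x[idx, , , drop = FALSE], valid_len = fs$valid_len[idx],
       ids = fs$ids[idx], labels = fs$labels[idx],
       tokens = fs$tokens[idx], config = fs$config)
}

#' Train the network with mini-batch stochastic gradient descent
#'
#' Reproducible given the seed in `config` (same shuffling and updates).
#' Per-epoch training loss and validation ROC-AUC are recorded in the
#' returned history.
#'
#' @param model an untrained (or partially trained) `scfp_model`.
#' @param train_set,valid_set featurized datasets from [featurize_dataset()];
#'   `valid_set` may be `NULL` (no per-epoch AUC).
#' @param config a [scfp_train_config()].
#' @param log optional connection/file to stream per-epoch metrics to.
#' @param verbose print per-epoch metrics.
#' @return list with `model` (trained) and `history` (data frame `epoch`,
#'   `loss`, `val_auc`, `seconds`).
#' @export
train_scfp <- function(model, train_set, valid_set = NULL,
                       config = scfp_train_config(), log = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(model, "scfp_model"),
            inherits(config, "scfp_train_config"))
  y <- train_set$labels
  if (is.null(y)) stop("training set has no labels", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training labels are degenerate (single class)", call. = FALSE)
  n <- dim(train_set$x)[1]
  set.seed(config$seed)
  stepper <- make_optimizer(config$optimizer, config$learning_rate)

  hist_loss <- numeric(0); hist_auc <- numeric(0); hist_sec <- numeric(0)
  best_auc <- -Inf; since_best <- 0L
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = config$minibatch_size)) {
      idx <- ord[start:min(start + config$minibatch_size - 1L, n)]
      fw <- scfp_forward(model, train_set$x[idx, , , drop = FALSE],
                         valid_len = train_set$valid_len[idx],
                         cache = TRUE, training = TRUE)
      bw <- scfp_backward(model, fw, y[idx], loss = config$loss,
                          pos_weight = config$pos_weight)
      if (model$config$batch_norm) {
        model$bn1$mean <- fw$cache$bn1$new_mean
        model$bn1$var <- fw$cache$bn1$new_var
        model$bn2$mean <- fw$cache$bn2$new_mean
        model$bn2$var <- fw$cache$bn2$new_var
      }
      model <- apply_grad_step(model, bw$grads, stepper)
      losses <- c(losses, bw$loss)
    }
    val_auc <- NA_real_
    if (!is.null(valid_set)) {
      fwv <- scfp_forward(model, valid_set$x, valid_set$valid_len)
      val_auc <- roc_auc(valid_set$labels, fwv$scores)
    }
    secs <- proc.time()[["elapsed"]] - t0
    hist_loss <- c(hist_loss, mean(losses))
    hist_auc <- c(hist_auc, val_auc)
    hist_sec <- c(hist_sec, secs)
    msg <- sprintf("epoch %d loss %.5f val_auc %s (%.2fs)", epoch,
                   mean(losses), ifelse(is.na(val_auc), "NA",
                                        sprintf("%.4f", val_auc)), secs)
    if (verbose) message(msg)
    if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE)
    if (!is.null(config$patience) && !is.na(val_auc)) {
      if (val_auc > best_auc + 1e-12) {
        best_auc <- val_auc; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  }
  model$trained <- TRUE
  list(model = model,
       history = data.frame(epoch = seq_along(hist_loss), loss = hist_loss,
                            val_auc = hist_auc, seconds = hist_sec))
}

#' Rank-based ROC-AUC
#'
#' Area under the receiver operating characteristic curve: the probability
#' that a random positive outscores a random negative (ties count 1/2).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("ROC-AUC is undefined: only one class present", call. = FALSE)
  as.numeric(pROC::auc(pROC::roc(labels, as.numeric(scores),
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Evaluate a model's ROC-AUC on a featurized dataset
#'
#' @param model an `scfp_model`.
#' @param dataset featurized dataset from [featurize_dataset()] with labels.
#' @return AUC in \[0, 1\].
#' @export
evaluate_roc_auc <- function(model, dataset) {
  if (is.null(dataset$labels))
    stop("dataset has no labels", call. = FALSE)
  fw <- scfp_forward(model, dataset$x, dataset$valid_len)
  roc_auc(dataset$labels, fw$scores)
}

#' Label-stratified fold assignment
#'
#' Each class is shuffled and dealt round-robin over the folds, so per-class
#' fold sizes differ by at most one compound.
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..k) per compound.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < k))
    stop("cannot stratify: class '", names(tab)[which.min(tab)], "' has ",
         min(tab), " members for k = ", k, " folds", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    idx <- members[sample.int(length(members))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Five-fold cross validation
#'
#' Stratified k-fold protocol: each compound is scored exactly once, by the
#' model trained on the other folds.
#'
#' @param compounds data frame with `id`, `smiles`, `label`.
#' @param model_config a [scfp_model_config()].
#' @param train_config a [scfp_train_config()].
#' @param k number of folds (default 5).
#' @param seed seed for fold assignment and per-fold model initialization.
#' @param max_len featurizer rows; `NULL` = dataset maximum token count.
#' @return list with `fold_auc`, `mean_auc`, `sd_auc`, `folds` (assignment),
#'   and `histories`.
#' @export
cross_validate <- function(compounds, model_config = scfp_model_config(),
                           train_config = scfp_train_config(), k = 5L,
                           seed = 1L, max_len = NULL) {
  if (nrow(compounds) < k) stop("dataset smaller than k", call. = FALSE)
  cfgf <- if (is.null(max_len)) NULL else featurizer_config(max_len)
  fs <- featurize_dataset(compounds, cfgf)
  folds <- stratified_folds(fs$labels, k, seed)
  aucs <- numeric(k)
  hists <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- subset_featurized(fs, folds != f)
    va <- subset_featurized(fs, folds == f)
    model <- build_model(model_config, seed = seed + f)
    tc <- train_config
    tc$seed <- train_config$seed + f
    fit <- train_scfp(model, tr, va, tc)
    aucs[f] <- evaluate_roc_auc(fit$model, va)
    hists[[f]] <- fit$history
  }
  list(fold_auc = aucs, mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
       folds = folds, histories = hists)
}
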