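# Motif detection -------------------------------------------------------------
#
# Each of the 64 fingerprint dimensions is a max-pooled convolution filter
# response.  A filter whose response on a compound is unusually high relative
# to a background distribution marks a learned structural feature; tracing
# the argmax position back through the network's receptive field yields the
# contributing SMILES substring and atoms.

#' Fit per-filter background statistics
#'
#' Computes the mean and standard deviation of each fingerprint dimension
#' over a background dataset, for z-score normalization.  Filters with zero
#' variance are flagged and excluded from detection.
#'
#' @param model a trained `scfp_model`.
#' @param dataset a featurized dataset from [featurize_dataset()].
#' @return a `scfp_filter_stats` list: `mean`, `sd` (length-`n_filters`
#'   numeric, sample standard deviation), `zero_variance` (logical), `n`.
#' @export
fit_filter_stats <- function(model, dataset) {
  scfp <- scfp_forward(model, dataset$x, valid_len = dataset$valid_len)$scfp
  n <- nrow(scfp)
  if (n < 2L) stop("need at least 2 background compounds", call. = FALSE)
  mu <- colMeans(scfp)
  sdv <- apply(scfp, 2L, stats::sd)
  zero <- !is.finite(sdv) | sdv < .Machine$double.eps^0.5
  if (any(zero))
    warning(sum(zero), " filter(s) have zero variance on the background ",
            "set and are excluded from detection")
  structure(list(mean = mu, sd = sdv, zero_variance = zero, n = n),
            class = "scfp_filter_stats")
}

#' @export
print.scfp_filter_stats <- function(x, ...) {
  cat("<scfp_filter_stats> ", length(x$mean), " filters, fit on ", x$n,
      " compounds (", sum(x$zero_variance), " zero-variance)\n", sep = "")
  invisible(x)
}

#' Z-score normalize fingerprints
#'
#' @param scfp fingerprint matrix (compounds x filters), e.g. from
#'   [compute_scfp()].
#' @param stats a [fit_filter_stats()] object.
#' @return matrix of z-scores; zero-variance filters are `NA`.
#' @export
normalize_scfp <- function(scfp, stats) {
  stopifnot(inherits(stats, "scfp_filter_stats"),
            ncol(scfp) == length(stats$mean))
  z <- sweep(sweep(scfp, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  z[, stats$zero_variance] <- NA_real_
  z
}

#' Detect motifs in compounds
#'
#' For each compound, finds filters whose fingerprint value exceeds
#' `threshold` background standard deviations above the background mean
#' (`z > threshold`; the default threshold 2.58 corresponds to the upper
#' 0.5% tail of a normal background).  Each detection is traced back from the filter's
#' max-pooling argmax position through the network's receptive field to a
#' SMILES substring and its atoms.
#'
#' @param model a trained `scfp_model`.
#' @param dataset a featurized dataset from [featurize_dataset()] (its
#'   `tokens` are needed to report substrings and atoms).
#' @param stats background statistics from [fit_filter_stats()].
#' @param threshold z-score threshold (default 2.58).
#' @return a `scfp_motifs` data frame, one row per (compound, filter)
#'   detection, sorted by compound then decreasing z: `compound_id`,
#'   `filter`, `z`, `span_start`, `span_end` (1-based inclusive token
#'   positions), `substring` (SMILES characters under the span), and a list
#'   column `atom_ordinals` (atoms of the ATOM tokens in the span).
#' @export
detect_motifs <- function(model, dataset, stats, threshold = 2.58) {
  stopifnot(inherits(model, "scfp_model"),
            inherits(stats, "scfp_filter_stats"))
  fw <- scfp_forward(model, dataset$x, valid_len = dataset$valid_len)
  z <- normalize_scfp(fw$scfp, stats)
  nfil <- ncol(z)
  rows <- list()
  for (i in seq_len(nrow(z))) {
    hit <- which(!is.na(z[i, ]) & z[i, ] > threshold)
    if (!length(hit)) next
    hit <- hit[order(z[i, hit], decreasing = TRUE)]
    tk <- dataset$tokens[[i]]
    vl <- dataset$valid_len[i]
    for (f in hit) {
      span <- traceback_span(model$config, fw$argmax[i, f],
                             input_len = dim(dataset$x)[2], valid_len = vl)
      sub_tokens <- tk$tokens[span[1]:span[2], , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = dataset$ids[i], filter = f, z = z[i, f],
        span_start = span[1], span_end = span[2],
        substring = substr(tk$canonical_smiles,
                           sub_tokens$start[1] + 1L,
                           sub_tokens$end[nrow(sub_tokens)]),
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$atom_ordinals <-
        list(sub_tokens$atom_ordinal[sub_tokens$kind == "ATOM"])
    }
  }
  out <- if (length(rows)) {
    o <- do.call(rbind, rows)
    rownames(o) <- NULL
    o
  } else
    data.frame(compound_id = character(0), filter = integer(0),
               z = numeric(0), span_start = integer(0),
               span_end = integer(0), substring = character(0),
               atom_ordinals = I(list()))
  structure(out, threshold = threshold,
            class = c("scfp_motifs", "data.frame"))
}

#' Write a motif report as tab-separated text
#'
#' @param motifs a [detect_motifs()] result.
#' @param path output file.
#' @export
write_motif_report <- function(motifs, path) {
  stopifnot(inherits(motifs, "scfp_motifs"))
  df <- as.data.frame(motifs[, c("compound_id", "filter", "z",
                                 "span_start", "span_end", "substring")])
  df$atom_ordinals <- vapply(motifs$atom_ordinals,
                             function(a) paste(a, collapse = ";"), "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ECFP fingerprints via Open Babel
#'
#' Circular (ECFP4-class) fingerprints folded to `n_bits` for baseline
#' comparisons with the learned fingerprint.
#'
#' @param smiles character vector of SMILES.
#' @param n_bits folded width (default 1024).
#' @return binary matrix, compounds x bits.
#' @export
ecfp_fingerprints <- function(smiles, n_bits = 1024L) {
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  stopifnot(ncol(fp) %% n_bits == 0L)
  folds <- ncol(fp) / n_bits
  out <- matrix(0L, nrow(fp), n_bits)
  for (k in seq_len(folds))
    out <- out | fp[, seq_len(n_bits) + (k - 1L) * n_bits, drop = FALSE]
  mode(out) <- "integer"
  rownames(out) <- smiles
  out
}

#' Low-dimensional embedding of chemical space
#'
#' Classical multidimensional scaling of Euclidean distances between
#' fingerprint rows, for visual comparison of fingerprint spaces.
#'
#' @param fingerprints numeric matrix (compounds x dimensions), e.g. a
#'   learned fingerprint matrix or [ecfp_fingerprints()].
#' @param k embedding dimension (default 2).
#' @return matrix, compounds x `k`.
#' @export
embed_chemical_space <- function(fingerprints, k = 2L) {
  stopifnot(nrow(fingerprints) >= 3L)
  stats::cmdscale(stats::dist(fingerprints), k = k)
}
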