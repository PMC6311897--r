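# Compound and fingerprint IO -------------------------------------------------

#' Read a compound dataset
#'
#' `"smiles-tsv"` is tab-separated text with columns `id`, `smiles` and
#' optionally `label` (0/1), a header line, and `#` comment lines.  `"sdf"`
#' reads an SD file via ChemmineR; labels are taken from an `label` data
#' field when present.
#'
#' @param path input file.
#' @param format `"smiles-tsv"` (default, inferred from extension) or
#'   `"sdf"`.
#' @param strict if `TRUE`, malformed records are errors; otherwise they are
#'   skipped with a warning naming the offending lines.
#' @return data frame with columns `id`, `smiles` and, if present, `label`.
#' @export
read_compounds <- function(path, format = c("auto", "smiles-tsv", "sdf"),
                           strict = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf"
              else "smiles-tsv"
  if (format == "sdf") return(read_compounds_sdf(path))

  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no records in ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("id", "smiles") %in% header))
    stop("header must contain 'id' and 'smiles' columns (got: ",
         paste(header, collapse = ", "), ")", call. = FALSE)
  body <- lines[-1]; lineno <- lineno[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- nfield != length(header)
  df <- do.call(rbind, lapply(parts[!bad], function(p)
    as.data.frame(as.list(p), col.names = header,
                  stringsAsFactors = FALSE)))
  bad_lines <- lineno[bad]
  if (!is.null(df) && "label" %in% header) {
    lab <- suppressWarnings(as.integer(df$label))
    badlab <- is.na(lab) | !(lab %in% c(0L, 1L))
    bad_lines <- sort(c(bad_lines, lineno[!bad][badlab]))
    df <- df[!badlab, , drop = FALSE]
    df$label <- lab[!badlab]
  }
  if (length(bad_lines)) {
    msg <- paste0(length(bad_lines), " malformed record(s) at line(s) ",
                  paste(utils::head(bad_lines, 10L), collapse = ", "),
                  " of ", path)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (is.null(df) || !nrow(df)) stop("no valid records in ", path, call. = FALSE)
  rownames(df) <- NULL
  df
}

read_compounds_sdf <- function(path) {
  set <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(set)
  smi <- as.character(ChemmineR::sdf2smiles(set))
  df <- data.frame(id = ids, smiles = smi, stringsAsFactors = FALSE)
  blocks <- ChemmineR::datablock(set)
  labs <- vapply(blocks, function(b)
    if ("label" %in% names(b)) as.character(b[["label"]]) else NA_character_,
    "")
  if (!all(is.na(labs))) df$label <- as.integer(labs)
  df
}

#' Write a compound dataset
#'
#' @param compounds data frame with `id`, `smiles`, optionally `label`.
#' @param path output file.
#' @param format `"smiles-tsv"` or `"sdf"` (SD file via ChemmineR, with a
#'   `label` data field when labels are present).
#' @export
write_compounds <- function(compounds, path,
                            format = c("smiles-tsv", "sdf")) {
  format <- match.arg(format)
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  cols <- intersect(c("id", "smiles", "label"), names(compounds))
  if (format == "smiles-tsv") {
    utils::write.table(compounds[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    set <- ChemmineR::smiles2sdf(stats::setNames(compounds$smiles,
                                                 compounds$id))
    if ("label" %in% cols)
      ChemmineR::datablock(set) <- lapply(compounds$label,
                                          function(l) c(label = as.character(l)))
    ChemmineR::write.SDF(set, path)
  }
  invisible(path)
}

#' Write fingerprints as tab-separated text
#'
#' @param scfp fingerprint matrix (compounds x filters) with compound ids as
#'   row names, e.g. from [compute_scfp()].
#' @param path output file.  Columns: `id`, then `scfp_0` ... (zero-based
#'   filter indices), written at full precision.
#' @export
write_fingerprints <- function(scfp, path) {
  df <- data.frame(id = rownames(scfp) %||% as.character(seq_len(nrow(scfp))),
                   stringsAsFactors = FALSE)
  m <- as.data.frame(scfp)
  names(m) <- paste0("scfp_", seq_len(ncol(scfp)) - 1L)
  utils::write.table(cbind(df, m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read fingerprints written by [write_fingerprints()]
#'
#' @param path input file.
#' @return numeric matrix with compound ids as row names.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
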