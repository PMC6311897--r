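# Locate the OpenBabel executable once per session.
ob_binary <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      path <- Sys.which("obabel")
      if (!nzchar(path)) {
        stop("OpenBabel ('obabel') was not found on the PATH; it is required ",
             "for SMILES canonicalization.", call. = FALSE)
      }
      cached <<- unname(path)
    }
    cached
  }
})

# Run one batched obabel conversion of SMILES strings.  Inputs are tagged with
# numeric titles so outputs can be re-aligned when some molecules fail to
# parse (obabel -e skips them).  Returns a character vector aligned with
# `smiles`, NA where conversion failed.
ob_smiles_convert <- function(smiles, kekule = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  bad <- is.na(smiles) | !nzchar(smiles) | grepl("[[:space:]]", smiles)
  out <- rep(NA_character_, length(smiles))
  idx <- which(!bad)
  if (length(idx) == 0L) return(out)

  infile <- tempfile(fileext = ".smi")
  on.exit(unlink(infile), add = TRUE)
  writeLines(paste(smiles[idx], seq_along(idx)), infile)

  args <- c(infile, "-ocan", "-e")
  if (kekule) args <- c(args, "-xk")
  # stderr must be kept separate: merging the streams can interleave a
  # warning into the middle of an output line and corrupt it
  errfile <- tempfile(fileext = ".err")
  on.exit(unlink(errfile), add = TRUE)
  res <- suppressWarnings(system2(ob_binary(), args, stdout = TRUE,
                                  stderr = errfile))
  status <- attr(res, "status")
  lines <- grep("\t", res, fixed = TRUE, value = TRUE)
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(parts, length, 1L) >= 2L
    parts <- parts[ok]
    tags <- suppressWarnings(as.integer(trimws(vapply(parts, `[[`, "", 2L))))
    smis <- vapply(parts, `[[`, "", 1L)
    keep <- !is.na(tags) & tags >= 1L & tags <= length(idx)
    out[idx[tags[keep]]] <- smis[keep]
  }
  if (!is.null(status) && status != 0L && all(is.na(out[idx]))) {
    err <- tryCatch(readLines(errfile, warn = FALSE), error = function(e) "")
    stop("obabel failed: ", paste(utils::head(err, 3L), collapse = " "),
         call. = FALSE)
  }
  out
}

#' Canonicalize SMILES strings
#'
#' Converts arbitrary valid SMILES into the toolkit's canonical, Kekulé-form
#' SMILES (uppercase atoms, explicit double/triple bonds).  Two different
#' SMILES spellings of the same molecule canonicalize to the same string, and
#' the function is idempotent.  Aromaticity is not lost: it is re-perceived by
#' the featurizer as a per-atom feature rather than being carried by lowercase
#' atom symbols.
#'
#' @param smiles character vector of SMILES strings.
#' @param on_error `"error"` (default) stops naming the first offending input;
#'   `"na"` returns `NA` for inputs that fail to parse.
#' @return character vector of canonical Kekulé SMILES, same length as input.
#' @examples
#' \dontrun{
#' canonicalize_smiles("OC(=O)c1ccccc1OC(C)=O")  # aspirin
#' }
#' @export
canonicalize_smiles <- function(smiles, on_error = c("error", "na")) {
  on_error <- match.arg(on_error)
  # two passes: the toolkit's canonical Kekule string depends on whether the
  # input was written aromatic or Kekule, so normalize to the canonical
  # aromatic form first, then Kekulize that
  arom <- ob_smiles_convert(smiles, kekule = FALSE)
  out <- rep(NA_character_, length(arom))
  ok <- which(!is.na(arom))
  if (length(ok)) out[ok] <- ob_smiles_convert(arom[ok], kekule = TRUE)
  if (on_error == "error" && anyNA(out)) {
    bad <- smiles[which(is.na(out))[1L]]
    stop("SMILES could not be parsed/canonicalized: '", bad, "'",
         call. = FALSE)
  }
  out
}

# Aromatic-form canonical SMILES (lowercase aromatic atoms).  OpenBabel's
# canonical atom ranking does not depend on the Kekulé flag, so the i-th atom
# here corresponds to the i-th atom of the Kekulé canonical string; the
# featurizer relies on (and checks) this alignment to read aromaticity off
# the case of the atom symbols.
ob_aromatic_form <- function(smiles) {
  ob_smiles_convert(smiles, kekule = FALSE)
}
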