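# SMILES feature matrix -------------------------------------------------------
#
# Each SMILES symbol becomes a 42-dimensional feature vector: columns 1-21
# describe atoms (type one-hot, H count, degree, charge, valence, ring flag,
# aromaticity flag, chirality one-hot, hybridization one-hot), columns 22-42
# one-hot encode the 21 SMILES grammar symbols.  A compound is the row-wise
# stack of its token vectors, zero-padded to a fixed number of rows.

.atom_type_levels <- c("H", "C", "O", "N", "other")
.chirality_levels <- c("R", "S", "other")
.hybridization_levels <- c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2", "other")

#' Names of the 42 feature columns
#'
#' 21 atom features (`atom_*`, counts, flags, chirality and hybridization
#' one-hots) followed by the 21 grammar symbol features (`sym_*`).
#'
#' @return character vector of length 42.
#' @export
feature_names <- function() {
  c(paste0("atom_type_", .atom_type_levels),
    "num_hs", "degree", "charge", "valence", "in_ring", "aromatic",
    paste0("chirality_", .chirality_levels),
    paste0("hybridization_", .hybridization_levels),
    paste0("sym_", grammar_classes()))
}

#' Featurizer configuration
#'
#' @param max_len number of rows of the feature matrix; the default 400
#'   accommodates the longest SMILES in typical screening libraries.
#' @param on_overflow what to do when a SMILES has more tokens than
#'   `max_len`: `"error"` (default) or `"truncate"`.
#' @return a `scfp_featurizer_config` list.
#' @export
featurizer_config <- function(max_len = 400L, on_overflow = c("error", "truncate")) {
  on_overflow <- match.arg(on_overflow)
  max_len <- as.integer(max_len)
  if (is.na(max_len) || max_len < 1L) stop("max_len must be >= 1", call. = FALSE)
  structure(list(max_len = max_len, on_overflow = on_overflow),
            class = "scfp_featurizer_config")
}

#' Per-atom features of a molecule
#'
#' @param molecule an `scfp_molecule` from [smiles_molecule()].
#' @param atom_ordinal 1-based atom index in canonical-SMILES output order;
#'   `NULL` returns all atoms.
#' @return data frame with one row per requested atom: `atom_type`, `num_hs`,
#'   `degree`, `charge`, `valence`, `in_ring`, `aromatic`, `chirality`,
#'   `hybridization`.
#' @export
compute_atom_features <- function(molecule, atom_ordinal = NULL) {
  stopifnot(inherits(molecule, "scfp_molecule"))
  at <- molecule$atoms
  if (is.null(atom_ordinal)) atom_ordinal <- seq_len(nrow(at))
  if (any(atom_ordinal < 1L | atom_ordinal > nrow(at)))
    stop("atom_ordinal out of range (molecule has ", nrow(at), " atoms)",
         call. = FALSE)
  a <- at[atom_ordinal, , drop = FALSE]
  data.frame(
    atom_type = ifelse(a$element %in% .atom_type_levels, a$element, "other"),
    num_hs = a$num_h,
    degree = a$degree,
    charge = a$charge,
    valence = a$valence,
    in_ring = as.integer(a$in_ring),
    aromatic = as.integer(a$aromatic),
    chirality = ifelse(a$cip %in% c("R", "S"), a$cip, "other"),
    hybridization = ifelse(a$hybridization %in% .hybridization_levels,
                           a$hybridization, "other"),
    stringsAsFactors = FALSE)
}

#' Encode one token as a 42-dimensional feature vector
#'
#' ATOM tokens fill the atom block (columns 1-21) and zero the grammar block;
#' GRAMMAR tokens set exactly one grammar column to 1.
#'
#' @param token one row of an `scfp_tokens` token data frame (a list or
#'   one-row data frame with `kind` and `grammar_class`).
#' @param atom_features one row of [compute_atom_features()] output; required
#'   iff the token is an ATOM token.
#' @return numeric vector of length 42 named by [feature_names()].
#' @export
encode_token <- function(token, atom_features = NULL) {
  v <- stats::setNames(numeric(42L), feature_names())
  if (token$kind == "ATOM") {
    if (is.null(atom_features))
      stop("atom_features required for ATOM tokens", call. = FALSE)
    af <- atom_features
    v[paste0("atom_type_", af$atom_type)] <- 1
    v["num_hs"] <- af$num_hs
    v["degree"] <- af$degree
    v["charge"] <- af$charge
    v["valence"] <- af$valence
    v["in_ring"] <- af$in_ring
    v["aromatic"] <- af$aromatic
    v[paste0("chirality_", af$chirality)] <- 1
    v[paste0("hybridization_", af$hybridization)] <- 1
  } else {
    cls <- token$grammar_class
    col <- paste0("sym_", cls)
    if (is.na(cls) || !col %in% names(v))
      stop("unknown grammar class: ", cls, call. = FALSE)
    v[col] <- 1
  }
  v
}

#' Featurize one compound
#'
#' Canonicalizes, tokenizes and encodes a SMILES string into the fixed-size
#' feature matrix.  Deterministic: identical input gives a bit-identical
#' matrix.
#'
#' @param smiles a SMILES string.
#' @param config a [featurizer_config()].
#' @param compound_id identifier stored with the matrix.
#' @param canonical set `TRUE` if `smiles` is already canonical Kekulé form.
#' @return a `scfp_matrix`: numeric matrix `max_len x 42` with attributes
#'   `valid_len`, `compound_id`, `tokens` (the `scfp_tokens` object).
#' @export
featurize_smiles <- function(smiles, config = featurizer_config(),
                             compound_id = smiles, canonical = FALSE) {
  mol <- smiles_molecule(smiles, canonical = canonical)
  featurize_molecule(mol, config, compound_id)
}

featurize_molecule <- function(mol, config = featurizer_config(),
                               compound_id = "") {
  tokens <- mol$tokens$tokens
  n <- nrow(tokens)
  if (n > config$max_len) {
    if (config$on_overflow == "error")
      stop("compound '", compound_id, "' has ", n,
           " tokens, exceeding max_len = ", config$max_len, call. = FALSE)
    n <- config$max_len
  }
  af <- compute_atom_features(mol)
  m <- matrix(0, nrow = config$max_len, ncol = 42L,
              dimnames = list(NULL, feature_names()))
  for (k in seq_len(n)) {
    if (tokens$kind[k] == "ATOM") {
      m[k, ] <- encode_token(tokens[k, ], af[tokens$atom_ordinal[k], , drop = FALSE])
    } else {
      m[k, ] <- encode_token(tokens[k, ])
    }
  }
  structure(m, valid_len = n, compound_id = compound_id,
            tokens = mol$tokens, class = c("scfp_matrix", "matrix", "array"))
}

#' Featurize a dataset of compounds
#'
#' @param compounds data frame with columns `id`, `smiles` and optionally
#'   `label` (0/1), e.g. from [read_compounds()] or
#'   [generate_planted_dataset()].
#' @param config a [featurizer_config()]; `max_len = NULL` uses the dataset
#'   maximum token count, which avoids computing over padding rows that no
#'   compound in the dataset needs.
#' @param on_invalid `"error"` or `"skip"` (skip unparseable compounds with a
#'   warning).
#' @return list with `x` (3-d array `n x max_len x 42`), `valid_len` (integer
#'   vector), `ids`, `labels` (or `NULL`), `tokens` (list of `scfp_tokens`).
#' @export
featurize_dataset <- function(compounds, config = NULL,
                              on_invalid = c("error", "skip")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.data.frame(compounds), nrow(compounds) > 0L,
            all(c("id", "smiles") %in% names(compounds)))
  can <- canonicalize_smiles(compounds$smiles, on_error = "na")
  bad <- which(is.na(can))
  if (length(bad)) {
    if (on_invalid == "error")
      stop("unparseable SMILES for compound '", compounds$id[bad[1]], "'",
           call. = FALSE)
    warning(length(bad), " compound(s) skipped as unparseable: ",
            paste(utils::head(compounds$id[bad], 5L), collapse = ", "))
    compounds <- compounds[-bad, , drop = FALSE]
    can <- can[-bad]
  }
  if (!nrow(compounds)) stop("no valid compounds in dataset", call. = FALSE)

  mols <- lapply(can, smiles_molecule, canonical = TRUE)
  n_tok <- vapply(mols, function(m) nrow(m$tokens$tokens), 1L)
  if (is.null(config)) config <- featurizer_config(max_len = max(n_tok))

  x <- array(0, dim = c(nrow(compounds), config$max_len, 42L),
             dimnames = list(compounds$id, NULL, feature_names()))
  vl <- integer(nrow(compounds))
  toks <- vector("list", nrow(compounds))
  for (i in seq_along(mols)) {
    fm <- featurize_molecule(mols[[i]], config, compounds$id[i])
    x[i, , ] <- fm
    vl[i] <- attr(fm, "valid_len")
    toks[[i]] <- attr(fm, "tokens")
  }
  labels <- if ("label" %in% names(compounds)) compounds$label else NULL
  list(x = x, valid_len = vl, ids = compounds$id, labels = labels,
       tokens = toks, config = config)
}

#' Write a feature matrix as tab-separated text
#'
#' One row per token (padding rows omitted), 42 named columns, for
#' inspection.
#'
#' @param m a `scfp_matrix` from [featurize_smiles()].
#' @param path output file.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(inherits(m, "scfp_matrix"))
  vl <- attr(m, "valid_len")
  df <- as.data.frame(unclass(m)[seq_len(vl), , drop = FALSE])
  df <- cbind(token = attr(m, "tokens")$tokens$text[seq_len(vl)], df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
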