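# SMILES tokenizer ------------------------------------------------------------
#
# Splits a canonical Kekulé SMILES string into typed tokens: ATOM tokens (one
# per heavy atom or standalone [H]) and GRAMMAR tokens drawn from the 21-symbol
# grammar inventory used by the featurizer.  Character offsets are 0-based,
# half-open throughout.

#' The 21 SMILES grammar symbol classes
#'
#' Order defines the grammar block (columns 22-42) of the feature matrix:
#' branch open/close, bracket open/close, ionic bond ".", aromatic bond ":",
#' double bond "=", triple bond "#", cis "\\", trans "/", chirality "@",
#' cation "+", anion "-", ionic charge magnitudes 2-7, ring start, ring end.
#'
#' @return character vector of length 21.
#' @export
grammar_classes <- function() {
  c("branch_open", "branch_close", "bracket_open", "bracket_close",
    "ionic_bond", "aromatic_bond", "double_bond", "triple_bond",
    "cis", "trans", "chirality", "cation", "anion",
    paste0("charge", 2:7), "ring_start", "ring_end")
}

# single-character grammar symbols outside of ring/charge handling
.grammar_chars <- c(
  "(" = "branch_open", ")" = "branch_close",
  "[" = "bracket_open", "]" = "bracket_close",
  "." = "ionic_bond", ":" = "aromatic_bond",
  "=" = "double_bond", "#" = "triple_bond",
  "\\" = "cis", "/" = "trans",
  "+" = "cation", "-" = "anion")

# elements written without brackets in SMILES (organic subset), longest first
.organic_two <- c("Cl", "Br")
.organic_one <- c("B", "C", "N", "O", "P", "S", "F", "I")
.aromatic_one <- c("b", "c", "n", "o", "p", "s")

#' Tokenize a canonical SMILES string
#'
#' Walks the string character by character and emits one token per SMILES
#' symbol: two-letter elements (`Cl`, `Br`, ...) are single ATOM tokens;
#' ring-closure digits (including `%nn`) are GRAMMAR tokens classed
#' `ring_start` on first occurrence of a label and `ring_end` on the matching
#' occurrence (labels are reusable once closed); `@@` is a single chirality
#' token; digits 2-7 following a `+`/`-` inside brackets become ion-charge
#' tokens; a hydrogen count written inside a bracket atom is folded into that
#' atom's token (recorded as its explicit H count), while a standalone `[H]`
#' emits an ATOM token.
#'
#' @param smiles a single canonical (Kekulé-form) SMILES string, as returned
#'   by [canonicalize_smiles()].
#' @param allow_aromatic accept lowercase aromatic atom symbols (used
#'   internally to read the toolkit's aromatic form; the public contract is
#'   Kekulé input).
#' @return an object of class `scfp_tokens`: a list with `canonical_smiles`,
#'   `tokens` (data frame with columns `text`, `kind`, `grammar_class`,
#'   `atom_ordinal`, `start`, `end`), `atoms` (per-atom parse attributes) and
#'   `n_atoms`.  Offsets are 0-based half-open into `canonical_smiles`.
#' @export
tokenize_smiles <- function(smiles, allow_aromatic = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) stop("empty SMILES string", call. = FALSE)

  toks <- list()   # each: list(text, kind, grammar_class, atom_ordinal, start, end, extra)
  atoms <- list()  # each: list(element, aromatic, charge, explicit_h, bracket, chiral)
  open_rings <- list()  # label -> TRUE while open
  ring_starts <- character(0)
  ring_ends <- character(0)

  fail <- function(msg, pos0) {
    stop(sprintf("SMILES structural error at offset %d in '%s': %s",
                 pos0, smiles, msg), call. = FALSE)
  }
  push_tok <- function(tok) toks[[length(toks) + 1L]] <<- tok
  push_grammar <- function(text, class, start0, end0) {
    push_tok(list(text = text, kind = "GRAMMAR", grammar_class = class,
                  atom_ordinal = NA_integer_, start = start0, end = end0,
                  extra = NULL))
  }
  push_ring <- function(label, start0, end0, text) {
    if (!is.null(open_rings[[label]])) {
      open_rings[[label]] <<- NULL
      push_grammar(text, "ring_end", start0, end0)
    } else {
      open_rings[[label]] <<- TRUE
      push_grammar(text, "ring_start", start0, end0)
    }
  }
  push_atom <- function(element, aromatic, start0, end0, text,
                        charge = 0L, explicit_h = NA_integer_,
                        bracket = FALSE, chiral = "", extra = NULL) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = charge,
      explicit_h = explicit_h, bracket = bracket, chiral = chiral)
    push_tok(list(text = text, kind = "ATOM", grammar_class = NA_character_,
                  atom_ordinal = length(atoms), start = start0, end = end0,
                  extra = extra))
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""

    if (two %in% .organic_two) {
      push_atom(two, FALSE, i - 1L, i + 1L, two)
      i <- i + 2L
    } else if (ch %in% .organic_one) {
      push_atom(ch, FALSE, i - 1L, i, ch)
      i <- i + 1L
    } else if (ch %in% .aromatic_one) {
      if (!allow_aromatic)
        fail(paste0("aromatic atom '", ch, "' in Kekulé input"), i - 1L)
      push_atom(toupper(ch), TRUE, i - 1L, i, ch)
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      push_ring(ch, i - 1L, i, ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
        fail("'%' must be followed by two ring-label digits", i - 1L)
      lab <- paste0(chars[i + 1L], chars[i + 2L])
      push_ring(lab, i - 1L, i + 2L, paste0("%", lab))
      i <- i + 3L
    } else if (ch == "[") {
      i <- tokenize_bracket(chars, i, n, smiles, allow_aromatic,
                            push_grammar, push_atom, fail)
    } else if (ch %in% names(.grammar_chars)) {
      if (ch == "]") fail("unmatched ']'", i - 1L)
      push_grammar(ch, .grammar_chars[[ch]], i - 1L, i)
      i <- i + 1L
    } else {
      fail(paste0("unexpected character '", ch, "'"), i - 1L)
    }
  }

  if (length(open_rings))
    fail(paste0("unmatched ring label(s): ",
                paste(names(open_rings), collapse = ", ")), n)

  tokens <- data.frame(
    text = vapply(toks, `[[`, "", "text"),
    kind = vapply(toks, `[[`, "", "kind"),
    grammar_class = vapply(toks, `[[`, "", "grammar_class"),
    atom_ordinal = vapply(toks, `[[`, 1L, "atom_ordinal"),
    start = vapply(toks, `[[`, 1L, "start"),
    end = vapply(toks, `[[`, 1L, "end"),
    stringsAsFactors = FALSE)
  extra <- lapply(toks, `[[`, "extra")

  atom_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    charge = vapply(atoms, `[[`, 1L, "charge"),
    explicit_h = vapply(atoms, `[[`, 1L, "explicit_h"),
    bracket = vapply(atoms, `[[`, TRUE, "bracket"),
    chiral = vapply(atoms, `[[`, "", "chiral"),
    stringsAsFactors = FALSE)

  structure(list(canonical_smiles = smiles, tokens = tokens,
                 extra_spans = extra, atoms = atom_df,
                 n_atoms = nrow(atom_df)),
            class = "scfp_tokens")
}

# Parse one bracket atom starting at chars[i] == "[".  Emits the bracket-open
# token, the ATOM token (isotope digits and hydrogen count folded in), any
# chirality / charge grammar tokens, and the bracket-close token.  Returns the
# index of the first character after "]".
tokenize_bracket <- function(chars, i, n, smiles, allow_aromatic,
                             push_grammar, push_atom, fail) {
  start0 <- i - 1L
  close <- i + 1L
  while (close <= n && chars[close] != "]") close <- close + 1L
  if (close > n) fail("unclosed '['", start0)
  push_grammar("[", "bracket_open", start0, i)

  j <- i + 1L
  # isotope digits: parsed (kept in the atom token text) but carry no feature
  iso_start <- j
  while (j < close && grepl("[0-9]", chars[j])) j <- j + 1L

  # element symbol
  elem <- chars[j]
  aromatic <- FALSE
  if (grepl("[A-Z]", elem)) {
    if (j + 1L < close && grepl("[a-z]", chars[j + 1L])) {
      # two-letter element symbol (second letter lowercase; an uppercase 'H'
      # following the element is a hydrogen count, not part of the symbol)
      elem <- paste0(elem, chars[j + 1L])
      j <- j + 1L
    }
  } else if (grepl("[a-z]", elem)) {
    if (!allow_aromatic) fail("aromatic atom in Kekulé bracket", j - 1L)
    aromatic <- TRUE
    if (j + 1L < close && paste0(elem, chars[j + 1L]) %in% c("se", "as")) {
      elem <- paste0(elem, chars[j + 1L]); j <- j + 1L
    }
    elem <- paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
  } else {
    fail("expected element symbol in bracket", j - 1L)
  }
  atom_text_start <- iso_start - 1L
  atom_text_end <- j
  j <- j + 1L

  # remainder of the bracket: chirality, H count, charge (in textual order)
  pending <- list()  # grammar tokens to emit after the atom token
  explicit_h <- 0L
  charge <- 0L
  chiral <- ""
  extra <- NULL
  h_seen <- FALSE

  while (j < close) {
    ch <- chars[j]
    if (ch == "@") {
      if (j + 1L < close && chars[j + 1L] == "@") {
        pending[[length(pending) + 1L]] <-
          list(text = "@@", class = "chirality", s = j - 1L, e = j + 1L)
        chiral <- "@@"
        j <- j + 2L
      } else {
        pending[[length(pending) + 1L]] <-
          list(text = "@", class = "chirality", s = j - 1L, e = j)
        chiral <- "@"
        j <- j + 1L
      }
    } else if (ch == "H" && elem != "H") {
      hs <- j - 1L
      j <- j + 1L
      cnt <- ""
      while (j < close && grepl("[0-9]", chars[j])) {
        cnt <- paste0(cnt, chars[j]); j <- j + 1L
      }
      explicit_h <- if (nzchar(cnt)) as.integer(cnt) else 1L
      he <- j - 1L
      if (hs == atom_text_end) {
        atom_text_end <- he  # contiguous with the element: extend the span
      } else {
        extra <- rbind(extra, c(hs, he))  # e.g. [C@@H]: H after chirality
      }
      h_seen <- TRUE
    } else if (ch %in% c("+", "-")) {
      sign <- if (ch == "+") 1L else -1L
      cls <- if (ch == "+") "cation" else "anion"
      ss <- j - 1L
      j <- j + 1L
      run <- 1L
      while (j < close && chars[j] == ch) { run <- run + 1L; j <- j + 1L }
      pending[[length(pending) + 1L]] <-
        list(text = ch, class = cls, s = ss, e = ss + 1L)
      mag <- run
      if (run == 1L && j < close && grepl("[0-9]", chars[j])) {
        ds <- j - 1L
        dg <- ""
        while (j < close && grepl("[0-9]", chars[j])) {
          dg <- paste0(dg, chars[j]); j <- j + 1L
        }
        mag <- as.integer(dg)
        if (mag >= 2L && mag <= 7L) {
          pending[[length(pending) + 1L]] <-
            list(text = dg, class = paste0("charge", mag), s = ds, e = j - 1L)
        } else if (mag != 1L) {
          fail(paste0("unsupported charge magnitude ", mag), ds)
        }
      } else if (run > 1L) {
        # repeated signs normalized to sign + magnitude
        if (run > 7L) fail("unsupported charge magnitude", ss)
        pending[[length(pending) + 1L]] <-
          list(text = strrep(ch, run - 1L), class = paste0("charge", run),
               s = ss + 1L, e = ss + run)
      }
      charge <- sign * mag
    } else if (grepl("[0-9]", ch)) {
      fail("unexpected digit in bracket", j - 1L)
    } else {
      fail(paste0("unexpected character '", ch, "' in bracket"), j - 1L)
    }
  }

  if (elem == "H" && h_seen) fail("hydrogen count on a hydrogen atom", i)
  text <- paste(chars[(atom_text_start + 1L):atom_text_end], collapse = "")
  if (!is.null(extra))
    text <- paste0(text, paste(apply(extra, 1L, function(sp)
      paste(chars[(sp[1] + 1L):sp[2]], collapse = "")), collapse = ""))
  push_atom(elem, aromatic, atom_text_start, atom_text_end, text,
            charge = charge, explicit_h = explicit_h, bracket = TRUE,
            chiral = chiral, extra = extra)
  for (p in pending) push_grammar(p$text, p$class, p$s, p$e)
  push_grammar("]", "bracket_close", close - 1L, close)
  close + 1L
}

#' Reconstruct a SMILES string from its token spans
#'
#' Places every token's characters back at their recorded source offsets.
#' For bracket atoms whose hydrogen count is separated from the element by a
#' chirality mark (e.g. `[C@@H]`), the atom token owns two spans; simple text
#' concatenation is therefore only guaranteed to reproduce the input for
#' bracket-free strings, while this reconstruction is exact for all inputs.
#'
#' @param x an `scfp_tokens` object.
#' @return the reconstructed SMILES string.
#' @export
reconstruct_smiles <- function(x) {
  stopifnot(inherits(x, "scfp_tokens"))
  n <- nchar(x$canonical_smiles)
  out <- rep(NA_character_, n)
  src <- strsplit(x$canonical_smiles, "", fixed = TRUE)[[1]]
  fill <- function(s, e) out[(s + 1L):e] <<- src[(s + 1L):e]
  for (k in seq_len(nrow(x$tokens))) {
    fill(x$tokens$start[k], x$tokens$end[k])
    ex <- x$extra_spans[[k]]
    if (!is.null(ex)) for (r in seq_len(nrow(ex))) fill(ex[r, 1], ex[r, 2])
  }
  if (anyNA(out)) stop("token spans do not cover the input", call. = FALSE)
  paste(out, collapse = "")
}

#' @export
print.scfp_tokens <- function(x, ...) {
  cat("SMILES token sequence: ", x$canonical_smiles, "\n",
      nrow(x$tokens), " tokens, ", x$n_atoms, " atoms\n", sep = "")
  print(utils::head(x$tokens, 30L))
  invisible(x)
}
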