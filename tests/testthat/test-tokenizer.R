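test_that("canonicalization is idempotent and merges equivalent inputs", {
  asp <- canonicalize_smiles("OC(=O)c1ccccc1OC(C)=O")
  expect_identical(canonicalize_smiles(asp), asp)
  expect_false(grepl("[a-z]", gsub("Cl|Br", "", asp)))  # no aromatic atoms
  # two different valid writings of aspirin
  expect_identical(canonicalize_smiles("CC(=O)Oc1ccccc1C(O)=O"), asp)
  expect_identical(canonicalize_smiles("C"), "C")
  expect_error(canonicalize_smiles("C1CC"), "canonicalize")
  expect_true(is.na(canonicalize_smiles("not_a_smiles", on_error = "na")))
})

test_that("aspirin tokenizes to 24 tokens with correct classes", {
  tk <- tokenize_smiles("CC(=O)OC1=CC=CC=C1C(=O)O")
  expect_s3_class(tk, "scfp_tokens")
  expect_identical(nrow(tk$tokens), 24L)
  expect_identical(tk$n_atoms, 13L)
  kinds <- tk$tokens$kind
  expect_identical(sum(kinds == "ATOM"), 13L)
  # ring digit 1 occurs twice: first is ring_start, second ring_end
  ring <- tk$tokens[tk$tokens$text == "1", ]
  expect_identical(ring$grammar_class, c("ring_start", "ring_end"))
  # ATOM tokens carry atom ordinals 1..13 in order, grammar tokens NA
  expect_identical(tk$tokens$atom_ordinal[kinds == "ATOM"], 1:13)
  expect_true(all(is.na(tk$tokens$atom_ordinal[kinds != "ATOM"])))
})

test_that("token source spans are 0-based half-open and reconstruct input", {
  s <- "CC(=O)OC1=CC=CC=C1C(=O)O"
  tk <- tokenize_smiles(s)
  expect_identical(tk$tokens$start[1], 0L)
  for (i in seq_len(nrow(tk$tokens))) {
    sp <- substr(s, tk$tokens$start[i] + 1L, tk$tokens$end[i])
    expect_identical(sp, tk$tokens$text[i])
  }
  expect_identical(reconstruct_smiles(tk), s)
})

test_that("two-letter elements, %nn closures and label reuse are handled", {
  tk <- tokenize_smiles("ClCCBr")
  expect_identical(tk$tokens$text, c("Cl", "C", "C", "Br"))
  expect_identical(tk$n_atoms, 4L)
  # label reuse: 1 closes then reopens
  tk2 <- tokenize_smiles("C1CC1C1CC1")
  cls <- tk2$tokens$grammar_class[tk2$tokens$text == "1"]
  expect_identical(cls, c("ring_start", "ring_end", "ring_start", "ring_end"))
  # %10 ring label is one grammar token
  tk3 <- tokenize_smiles("C%10CCCC%10")
  pct <- tk3$tokens[grepl("%", tk3$tokens$text), ]
  expect_identical(nrow(pct), 2L)
  expect_identical(pct$grammar_class, c("ring_start", "ring_end"))
})

test_that("bracket atoms fold H and isotopes; charges become grammar tokens", {
  tk <- tokenize_smiles("[NH4+]")
  expect_identical(tk$n_atoms, 1L)
  at <- tk$tokens[tk$tokens$kind == "ATOM", ]
  expect_true(grepl("H4", at$text))
  expect_true("cation" %in% tk$tokens$grammar_class)
  # charge magnitude 2: "+" then ion-charge token "2"
  tk2 <- tokenize_smiles("[Ca+2]")
  expect_true(all(c("cation", "charge2") %in% tk2$tokens$grammar_class))
  # standalone [H] is an ATOM token
  tk3 <- tokenize_smiles("[H][H]")
  expect_identical(tk3$n_atoms, 2L)
  # chirality: @@ is a single token
  tk4 <- tokenize_smiles("N[C@@H](C)C(=O)O")
  expect_identical(sum(tk4$tokens$grammar_class %in% "chirality"), 1L)
  expect_identical(tk4$tokens$text[tk4$tokens$grammar_class %in% "chirality"],
                   "@@")
  expect_identical(reconstruct_smiles(tk4), "N[C@@H](C)C(=O)O")
})

test_that("grammar inventory has exactly the 21 documented classes", {
  g <- grammar_classes()
  expect_length(g, 21L)
  expect_true(all(c("branch_open", "branch_close", "bracket_open",
                    "bracket_close", "ionic_bond", "aromatic_bond",
                    "double_bond", "triple_bond", "cis", "trans",
                    "chirality", "cation", "anion", "ring_start",
                    "ring_end", paste0("charge", 2:7)) %in% g))
  expect_identical(anyDuplicated(g), 0L)
})

test_that("canonical forms agree with an independent toolkit on molecule identity", {
  pairs <- list(c("OCC", "CCO"), c("c1ccccc1", "C1=CC=CC=C1"),
                c("N(C)C", "CN(C)"), c("OC(=O)c1ccccc1OC(C)=O",
                                       "CC(=O)Oc1ccccc1C(=O)O"))
  for (p in pairs)
    expect_identical(canonicalize_smiles(p[1]), canonicalize_smiles(p[2]))
  # rdkit round trip: our canonical SMILES parse to the same molecule
  smi <- vapply(pairs, function(p) canonicalize_smiles(p[1]), "")
  out <- rdkit_run(smi, c(
    "for l in lines:",
    "    m = Chem.MolFromSmiles(l)",
    "    print('BAD' if m is None else Chem.MolToSmiles(m))"))
  expect_false(any(out == "BAD"))
  ref <- rdkit_run(vapply(pairs, `[`, "", 1L), c(
    "for l in lines:",
    "    print(Chem.MolToSmiles(Chem.MolFromSmiles(l)))"))
  expect_identical(out, ref)
})
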