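test_that("feature vector layout is 21 atom + 21 grammar columns", {
  fn <- feature_names()
  expect_length(fn, 42L)
  expect_identical(sum(startsWith(fn, "sym_")), 21L)
  expect_identical(sum(!startsWith(fn, "sym_")), 21L)
  expect_identical(fn[22:42], paste0("sym_", grammar_classes()))
})

test_that("atom features match an independent toolkit on reference molecules", {
  smi <- c("CCO", "CC(=O)OC1C=CC=CC=1C(=O)O", "C#N", "NC(=O)C1CC1",
           "CSC", "FC(F)(F)Cl")
  can <- canonicalize_smiles(smi)
  got <- do.call(rbind, lapply(can, function(s) {
    m <- smiles_molecule(s, canonical = TRUE)
    af <- compute_atom_features(m)
    data.frame(smiles = s, i = seq_len(nrow(af)), af)
  }))
  ref_lines <- rdkit_run(can, c(
    "for l in lines:",
    "    m = Chem.MolFromSmiles(l, sanitize=True)",
    "    for a in m.GetAtoms():",
    "        print(l, a.GetIdx()+1, a.GetSymbol(), a.GetTotalNumHs(),",
    "              a.GetDegree(), a.GetFormalCharge(), a.GetTotalValence(),",
    "              int(a.IsInRing()), int(a.GetIsAromatic()),",
    "              str(a.GetHybridization()).lower(), sep='\\t')"))
  ref <- read.table(text = ref_lines, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "",
                    col.names = c("smiles", "i", "elem", "num_hs", "degree",
                                  "charge", "valence", "in_ring", "aromatic",
                                  "hyb"))
  # rdkit atom order for MolFromSmiles follows the SMILES writing order
  expect_identical(nrow(got), nrow(ref))
  expect_equal(got$num_hs, ref$num_hs)
  expect_equal(got$degree, ref$degree)
  expect_equal(got$charge, ref$charge)
  expect_equal(got$valence, ref$valence)
  expect_equal(got$in_ring, ref$in_ring)
  expect_equal(got$aromatic, ref$aromatic)
  # the package uses a steric-number (VSEPR) hybridization rule; rdkit
  # additionally promotes conjugated heteroatoms (ester O, amide N) to sp2,
  # so cross-toolkit agreement is asserted on carbon atoms
  carbon <- ref$elem == "C"
  expect_identical(got$hybridization[carbon], ref$hyb[carbon])
})

test_that("heteroatom hybridization follows the steric-number rule", {
  # ester oxygen: 2 sigma neighbours + 2 lone pairs -> steric number 4 -> sp3
  af <- compute_atom_features(smiles_molecule("COC(C)=O"))
  expect_identical(af$hybridization[af$atom_type == "O" & af$degree == 2], "sp3")
  # carbonyl oxygen: 1 sigma neighbour + 2 lone pairs -> sp2
  expect_identical(af$hybridization[af$atom_type == "O" & af$degree == 1], "sp2")
  # nitrile nitrogen: 1 sigma + 1 lone pair -> sp
  af2 <- compute_atom_features(smiles_molecule("CC#N"))
  expect_identical(af2$hybridization[af2$atom_type == "N"], "sp")
})

test_that("chirality features match rdkit CIP labels", {
  smi <- c("N[C@@H](C)C(=O)O", "N[C@H](C)C(=O)O", "C[C@H]1CCCC[C@@H]1N")
  can <- canonicalize_smiles(smi)
  got <- unlist(lapply(can, function(s)
    compute_atom_features(smiles_molecule(s, canonical = TRUE))$chirality))
  ref_lines <- rdkit_run(can, c(
    "for l in lines:",
    "    m = Chem.MolFromSmiles(l)",
    "    Chem.AssignStereochemistry(m, cleanIt=True, force=True)",
    "    for a in m.GetAtoms():",
    "        print(a.GetPropsAsDict().get('_CIPCode', 'other'))"))
  expect_identical(got, ref_lines)
  # L-alanine's canonical form has exactly one R/S-labelled atom
  expect_identical(sum(got[1:6] != "other"), 1L)
})

test_that("token encoding separates atom and grammar blocks", {
  m <- featurize_smiles("CC(=O)O")
  expect_s3_class(m, "scfp_matrix")
  expect_identical(dim(m), c(400L, 42L))
  expect_identical(attr(m, "valid_len"), 7L)
  grammar_block <- unclass(m)[, 22:42]
  atom_block <- unclass(m)[, 1:21]
  tk <- attr(m, "tokens")$tokens
  is_atom <- tk$kind == "ATOM"
  # each token row is one-hot in exactly one block
  expect_true(all(rowSums(grammar_block[seq_len(7)[is_atom], , drop = FALSE]) == 0))
  expect_true(all(rowSums(grammar_block[seq_len(7)[!is_atom], , drop = FALSE]) == 1))
  expect_true(all(rowSums(atom_block[seq_len(7)[!is_atom], , drop = FALSE]) == 0))
  # padding rows are all-zero
  expect_true(all(unclass(m)[8:400, ] == 0))
  # determinism
  expect_identical(featurize_smiles("CC(=O)O"), m)
})

test_that("featurizer respects max_len and overflow policy", {
  long <- paste(rep("C", 30), collapse = "")
  cfg <- featurizer_config(max_len = 10L)
  expect_error(featurize_smiles(long, cfg), "max_len")
  cfg2 <- featurizer_config(max_len = 10L, on_overflow = "truncate")
  m <- featurize_smiles(long, cfg2)
  expect_identical(attr(m, "valid_len"), 10L)
  expect_error(featurizer_config(max_len = 0L), "max_len")
})

test_that("featurize_dataset defaults max_len to the dataset maximum", {
  d <- data.frame(id = c("a", "b", "c"),
                  smiles = c("CCO", "CCCCCCCC", "C"),
                  label = c(1L, 0L, 0L), stringsAsFactors = FALSE)
  fs <- featurize_dataset(d)
  expect_identical(dim(fs$x), c(3L, 8L, 42L))
  expect_identical(fs$valid_len, c(3L, 8L, 1L))
  expect_identical(fs$labels, c(1L, 0L, 0L))
  # invalid compounds: error by default, skip with warning when asked
  d2 <- rbind(d, data.frame(id = "bad", smiles = "xx(", label = 1L))
  expect_error(featurize_dataset(d2), "bad")
  expect_warning(fs2 <- featurize_dataset(d2, on_invalid = "skip"), "skip")
  expect_identical(fs2$ids, c("a", "b", "c"))
})
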