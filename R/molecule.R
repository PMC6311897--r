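# Molecular graph construction and atom perception ---------------------------
#
# Builds a molecular graph (atoms + bonds with integer orders) from a token
# sequence, then perceives the per-atom properties the featurizer needs:
# implicit hydrogen counts, connectivity degree, total valence, ring
# membership, aromaticity, hybridization, and CIP-style R/S labels.

# lowest standard valences used for implicit-hydrogen filling (organic subset)
.default_valences <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L)

# valence electrons of the neutral atom (for lone-pair counting)
.valence_electrons <- c(
  H = 1, B = 3, C = 4, Si = 4, N = 5, P = 5, As = 5, O = 6, S = 6, Se = 6,
  F = 7, Cl = 7, Br = 7, I = 7)

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, As = 33, Se = 34, Br = 35, I = 53)

#' Build a molecular graph from a SMILES string
#'
#' Canonicalizes (unless `canonical = TRUE`), tokenizes, and walks the token
#' sequence to assemble the bond list, resolving branches and ring closures.
#' Atom ordinals follow the order in which atoms appear in the canonical
#' SMILES, so the i-th ATOM token is the i-th atom of the graph.
#'
#' @param smiles a SMILES string.
#' @param canonical set to `TRUE` when `smiles` is already the output of
#'   [canonicalize_smiles()] (skips the toolkit round trip).
#' @param perceive_aromaticity read aromatic-atom flags from the toolkit's
#'   aromatic canonical form (requires the toolkit; set `FALSE` for raw
#'   parsing, e.g. of fragment patterns).
#' @return an object of class `scfp_molecule`: list with `tokens`
#'   (`scfp_tokens`), `atoms` (per-atom data frame with perception columns),
#'   and `bonds` (data frame `from`, `to`, `order`).
#' @export
smiles_molecule <- function(smiles, canonical = FALSE,
                            perceive_aromaticity = TRUE) {
  if (!canonical) smiles <- canonicalize_smiles(smiles)
  tk <- tokenize_smiles(smiles)
  mol <- build_graph(tk)
  if (perceive_aromaticity) {
    mol$atoms$aromatic <- aromatic_flags(smiles, mol)
  }
  mol <- perceive_atoms(mol)
  mol
}

# Walk tokens: branch stack, pending bond order, ring-closure table.
build_graph <- function(tk) {
  tokens <- tk$tokens
  atoms <- tk$atoms
  bonds_from <- integer(0); bonds_to <- integer(0); bonds_order <- numeric(0)
  add_bond <- function(a, b, ord) {
    bonds_from <<- c(bonds_from, a); bonds_to <<- c(bonds_to, b)
    bonds_order <<- c(bonds_order, ord)
  }
  prev <- NA_integer_
  stack <- integer(0)
  pending <- 1
  fresh <- FALSE          # "." seen: next atom starts a new component
  open <- list()          # ring label -> list(atom, order, slot)
  has_pred <- rep(FALSE, nrow(atoms))  # atom bonded to a preceding atom
  # neighbours of each atom in SMILES appearance order (ring partners count
  # at the position of the ring-closure digit); needed for chirality parity
  nbr <- vector("list", nrow(atoms))

  for (k in seq_len(nrow(tokens))) {
    kind <- tokens$kind[k]
    if (kind == "ATOM") {
      a <- tokens$atom_ordinal[k]
      if (!is.na(prev) && !fresh) {
        add_bond(prev, a, pending); has_pred[a] <- TRUE
        nbr[[prev]] <- c(nbr[[prev]], a); nbr[[a]] <- c(nbr[[a]], prev)
      }
      prev <- a; pending <- 1; fresh <- FALSE
    } else {
      cls <- tokens$grammar_class[k]
      if (cls == "branch_open") {
        stack <- c(stack, prev)
      } else if (cls == "branch_close") {
        if (!length(stack))
          stop("unmatched ')' at offset ", tokens$start[k], call. = FALSE)
        prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      } else if (cls == "double_bond") {
        pending <- 2
      } else if (cls == "triple_bond") {
        pending <- 3
      } else if (cls == "aromatic_bond") {
        pending <- 1.5
      } else if (cls == "ionic_bond") {
        fresh <- TRUE; prev <- NA_integer_; pending <- 1
      } else if (cls == "ring_start") {
        lab <- sub("^%", "", tokens$text[k])
        nbr[[prev]] <- c(nbr[[prev]], NA_integer_)  # partner not yet known
        open[[lab]] <- list(atom = prev, order = pending,
                            slot = length(nbr[[prev]]))
        pending <- 1
      } else if (cls == "ring_end") {
        lab <- sub("^%", "", tokens$text[k])
        op <- open[[lab]]
        open[[lab]] <- NULL
        ord <- max(op$order, pending)
        add_bond(op$atom, prev, ord)
        nbr[[op$atom]][op$slot] <- prev
        nbr[[prev]] <- c(nbr[[prev]], op$atom)
        pending <- 1
      }
      # cis/trans marks and "+"/"-" outside the graph walk are bond/charge
      # annotations with no effect on connectivity; bracket tokens likewise.
    }
  }
  bonds <- data.frame(from = bonds_from, to = bonds_to, order = bonds_order)
  atoms$has_pred <- has_pred
  structure(list(tokens = tk, atoms = atoms, bonds = bonds,
                 neighbour_order = nbr),
            class = "scfp_molecule")
}

# Per-atom aromaticity from the toolkit's aromatic canonical form.  The
# aromatic and Kekulé canonical strings of one molecule share the canonical
# atom order; the element sequences are compared as a guard.
aromatic_flags <- function(kekule_smiles, mol) {
  arom <- ob_aromatic_form(kekule_smiles)
  if (is.na(arom)) return(mol$atoms$aromatic)
  tk2 <- tokenize_smiles(arom, allow_aromatic = TRUE)
  if (tk2$n_atoms != nrow(mol$atoms) ||
      !all(tk2$atoms$element == mol$atoms$element)) {
    warning("atom order mismatch between Kekulé and aromatic canonical ",
            "forms; keeping parsed aromatic flags")
    return(mol$atoms$aromatic)
  }
  tk2$atoms$aromatic
}

# Fill perception columns: implicit/total H, degree, valence, ring, hybrid.
perceive_atoms <- function(mol) {
  at <- mol$atoms
  nb <- mol$bonds
  na_ <- nrow(at)
  bond_sum <- numeric(na_)
  degree <- integer(na_)
  if (nrow(nb)) {
    for (r in seq_len(nrow(nb))) {
      f <- nb$from[r]; t <- nb$to[r]; o <- nb$order[r]
      bond_sum[f] <- bond_sum[f] + o; bond_sum[t] <- bond_sum[t] + o
      degree[f] <- degree[f] + 1L; degree[t] <- degree[t] + 1L
    }
  }
  num_h <- integer(na_)
  for (i in seq_len(na_)) {
    if (at$bracket[i]) {
      num_h[i] <- max(0L, at$explicit_h[i], na.rm = TRUE)
    } else {
      dv <- .default_valences[[at$element[i]]]
      if (is.null(dv)) dv <- ceiling(bond_sum[i])
      # aromatic atoms parsed from a lowercase form carry one ring pi bond
      # counted at order 1.5 each; round the bond sum up before filling
      bs <- ceiling(bond_sum[i])
      fit <- dv[dv >= bs]
      num_h[i] <- if (length(fit)) fit[1] - bs else 0L
    }
  }
  at$num_h <- num_h
  at$degree <- degree
  at$valence <- as.integer(ceiling(bond_sum) + num_h)
  at$in_ring <- ring_membership(na_, nb)
  at$hybridization <- hybridization_labels(at, nb, bond_sum, degree, num_h)
  at$cip <- cip_labels(at, nb, num_h, mol$neighbour_order)
  mol$atoms <- at
  mol
}

# Atoms in at least one cycle = the 2-core of the graph (iteratively strip
# degree<=1 vertices; what survives is exactly the set of ring atoms).
ring_membership <- function(n_atoms, bonds) {
  if (n_atoms == 0L || nrow(bonds) == 0L) return(rep(FALSE, n_atoms))
  alive <- rep(TRUE, n_atoms)
  edge_alive <- rep(TRUE, nrow(bonds))
  repeat {
    deg <- integer(n_atoms)
    for (r in which(edge_alive)) {
      deg[bonds$from[r]] <- deg[bonds$from[r]] + 1L
      deg[bonds$to[r]] <- deg[bonds$to[r]] + 1L
    }
    drop <- alive & deg <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
    edge_alive <- edge_alive & alive[bonds$from] & alive[bonds$to]
  }
  alive
}

# Simplified VSEPR assignment: steric number = sigma neighbours (heavy + H)
# + lone pairs; SN 1 with no bonds -> s, 2 -> sp, 3 -> sp2, 4 -> sp3,
# 5 -> sp3d, 6 -> sp3d2.  Aromatic atoms are sp2.  Conjugative promotion of
# lone pairs (e.g. amide N, phenol O) is NOT modelled; see the vignette.
hybridization_labels <- function(at, bonds, bond_sum, degree, num_h) {
  n <- nrow(at)
  out <- character(n)
  for (i in seq_len(n)) {
    el <- at$element[i]
    if (el == "H") { out[i] <- "s"; next }
    if (at$aromatic[i]) { out[i] <- "sp2"; next }
    ve <- .valence_electrons[[el]]
    if (is.null(ve) || is.na(ve)) { out[i] <- "other"; next }
    sigma <- degree[i] + num_h[i]
    lp <- max(0, floor((ve - at$charge[i] - bond_sum[i] - num_h[i]) / 2))
    sn <- sigma + lp
    out[i] <- switch(as.character(sn),
                     "0" = "s", "1" = if (sigma == 0) "s" else "sp",
                     "2" = "sp", "3" = "sp2", "4" = "sp3",
                     "5" = "sp3d", "6" = "sp3d2", "other")
  }
  out
}

# CIP-style R/S labels for tetrahedral centres marked @/@@ in the SMILES.
# Substituent priorities are ranked by hierarchical-digraph comparison of
# atomic numbers (Cahn-Ingold-Prelog sphere ordering with duplicate atoms for
# multiple bonds); isotope and stereo-dependent tie-breaks are not applied,
# and unresolved ties yield "other".
cip_labels <- function(at, bonds, num_h, neighbour_order) {
  n <- nrow(at)
  out <- rep("other", n)
  centres <- which(nzchar(at$chiral))
  if (!length(centres)) return(out)

  adj <- vector("list", n)  # list of c(neighbour, order) in bond-file order
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      f <- bonds$from[r]; t <- bonds$to[r]; o <- bonds$order[r]
      adj[[f]] <- c(adj[[f]], list(c(t, o)))
      adj[[t]] <- c(adj[[t]], list(c(f, o)))
    }
  }
  z_of <- function(i) {
    z <- unname(.atomic_numbers[at$element[i]])
    if (is.na(z)) 0 else z
  }

  # Expand one CIP sphere: given current frontier nodes (atom index or 0 for
  # a duplicate/implicit-H phantom), return the sorted atomic numbers of the
  # next sphere and the new frontier.
  for (c0 in centres) {
    smiles_order <- neighbour_smiles_order(neighbour_order[[c0]], num_h[c0],
                                           at$has_pred[c0])
    if (length(smiles_order) != 4L) next  # not a plain tetrahedral centre

    ranks <- cip_rank_neighbours(c0, smiles_order, adj, z_of, num_h)
    if (anyNA(ranks) || anyDuplicated(ranks)) next  # unresolved tie

    # parity: sort SMILES-order neighbours into descending priority, counting
    # transpositions; "@" is odd orientation, "@@" even (see tests for the
    # geometric convention).
    perm <- order(ranks)  # ranks: 1 = highest priority
    swaps <- permutation_parity(perm)
    chi <- if (at$chiral[c0] == "@@") 1L else -1L
    if (swaps %% 2L == 1L) chi <- -chi
    out[c0] <- if (chi == 1L) "R" else "S"
  }
  out
}

# Neighbours of a chiral centre in SMILES appearance order (recorded during
# the graph walk; ring partners count at the position of the ring-closure
# digit).  The implicit bracket hydrogen (phantom index 0) is written right
# after the element, i.e. after the preceding neighbour if the centre has
# one, else first.
neighbour_smiles_order <- function(nbrs, nh, has_pred) {
  if (nh > 0L) {
    if (has_pred && length(nbrs) >= 1L) nbrs <- append(nbrs, 0L, after = 1L)
    else nbrs <- c(0L, nbrs)
  }
  nbrs
}

permutation_parity <- function(perm) {
  swaps <- 0L
  p <- perm
  for (i in seq_along(p)) {
    while (p[i] != i) {
      j <- p[i]
      p[c(i, j)] <- p[c(j, i)]
      swaps <- swaps + 1L
    }
  }
  swaps
}

# Rank the four substituents of a chiral centre (1 = highest CIP priority)
# by breadth-first sphere comparison of atomic-number multisets, duplicating
# atoms across multiple bonds and appending implicit hydrogens.
cip_rank_neighbours <- function(c0, nbrs, adj, z_of, num_h_vec) {
  keys <- lapply(nbrs, function(nb) cip_key(c0, nb, adj, z_of, num_h_vec))
  ranked <- rank_desc_keys(keys)
  ranked
}

# Build a comparable key: list of numeric vectors, one per sphere (sorted
# descending), up to a depth/width cap (ring traversal re-expands ancestors,
# so deep unresolved cases are declared ties rather than explored forever).
cip_key <- function(root, first, adj, z_of, num_h_vec, max_depth = 6L,
                    max_width = 512L) {
  if (first == 0L) {
    return(list(1))  # implicit hydrogen substituent
  }
  spheres <- list(c(z_of(first)))
  # frontier entries: list(atom, parent) ; phantoms have atom = -Z
  frontier <- list(c(first, root))
  for (d in seq_len(max_depth)) {
    nxt <- list()
    zs <- numeric(0)
    for (fr in frontier) {
      a <- fr[1]; parent <- fr[2]
      if (a < 0) next  # phantom: no substituents
      for (e in adj[[a]]) {
        b <- e[1]; o <- e[2]
        dup <- max(0L, round(o) - 1L)
        if (b != parent) {
          zs <- c(zs, z_of(b))
          nxt[[length(nxt) + 1L]] <- c(b, a)
        }
        if (dup > 0L) {
          zs <- c(zs, rep(z_of(b), dup))
          for (q in seq_len(dup)) nxt[[length(nxt) + 1L]] <- c(-z_of(b), a)
        }
      }
      if (num_h_vec[a] > 0L) zs <- c(zs, rep(1, num_h_vec[a]))
    }
    if (!length(zs)) break
    spheres[[length(spheres) + 1L]] <- sort(zs, decreasing = TRUE)
    frontier <- nxt
    if (!length(frontier) || length(frontier) > max_width) break
  }
  spheres
}

# Order keys descending; return ranks (1 = largest).  NA on exact ties.
rank_desc_keys <- function(keys) {
  n <- length(keys)
  cmp <- function(a, b) {
    for (d in seq_len(max(length(a), length(b)))) {
      va <- if (d <= length(a)) a[[d]] else numeric(0)
      vb <- if (d <= length(b)) b[[d]] else numeric(0)
      for (k in seq_len(max(length(va), length(vb)))) {
        xa <- if (k <= length(va)) va[k] else -1
        xb <- if (k <= length(vb)) vb[k] else -1
        if (xa != xb) return(sign(xa - xb))
      }
    }
    0L
  }
  ranks <- rep(NA_integer_, n)
  wins <- integer(n)
  tie <- FALSE
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    s <- cmp(keys[[i]], keys[[j]])
    if (s > 0) wins[i] <- wins[i] + 1L
    if (s == 0 && i < j) tie <- TRUE
  }
  if (tie) return(ranks)
  ranks <- n - wins
  ranks
}
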