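# Synthetic molecule generator ------------------------------------------------
#
# Random valence-respecting molecular graphs serialized to SMILES, with a
# chosen substructure planted into the "active" class.  Ground-truth motif
# atom positions are recomputed after canonicalization by substructure
# matching, so training, fingerprinting and motif recovery can be tested
# end-to-end without external data.

#' Generator parameters
#'
#' Defaults emulate the composition of a screening-assay subdataset: heavy
#' imbalance (about 1 active per 10 inactives), scaffolds of 8-30 heavy
#' atoms over a C/N/O/S/halogen alphabet, occasional branches, rings and
#' double bonds, and a carboxy-like planted fragment.
#'
#' @param n_active,n_inactive class sizes (defaults 50/500, about 1:10).
#' @param scaffold_atoms range of scaffold heavy-atom counts.
#' @param branch_prob probability a new atom attaches at a random eligible
#'   position rather than extending the current chain tip.
#' @param ring_prob per-candidate probability of closing a ring.
#' @param double_bond_prob probability a new bond is a double bond (when
#'   valences allow).
#' @param alphabet named numeric vector of element sampling weights.
#' @param planted_motif SMILES fragment embedded in every active compound;
#'   its first atom is the attachment point.
#' @param seed RNG seed.
#' @return a `scfp_gen_params` list.
#' @export
scfp_gen_params <- function(n_active = 50L, n_inactive = 500L,
                            scaffold_atoms = c(8L, 30L),
                            branch_prob = 0.3, ring_prob = 0.2,
                            double_bond_prob = 0.1,
                            alphabet = c(C = 0.70, N = 0.12, O = 0.12,
                                         S = 0.03, F = 0.015, Cl = 0.01,
                                         Br = 0.005),
                            planted_motif = "C(=O)O", seed = 1L) {
  stopifnot(n_active >= 0, n_inactive >= 0, length(scaffold_atoms) == 2L,
            scaffold_atoms[1] >= 1L, scaffold_atoms[2] >= scaffold_atoms[1],
            all(alphabet > 0), !is.null(names(alphabet)))
  frag <- tokenize_smiles(planted_motif)  # must at least tokenize
  if (frag$n_atoms < 1L) stop("planted_motif has no atoms", call. = FALSE)
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 scaffold_atoms = as.integer(scaffold_atoms),
                 branch_prob = branch_prob, ring_prob = ring_prob,
                 double_bond_prob = double_bond_prob,
                 alphabet = alphabet / sum(alphabet),
                 planted_motif = planted_motif, seed = as.integer(seed)),
            class = "scfp_gen_params")
}

.max_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, B = 3L,
                  F = 1L, Cl = 1L, Br = 1L, I = 1L)

# Random valence-respecting graph: elements, bonds (from,to,order).
random_graph <- function(params) {
  sizes <- params$scaffold_atoms[1]:params$scaffold_atoms[2]
  n <- sizes[sample.int(length(sizes), 1L)]
  el <- character(n); from <- integer(0); to <- integer(0); ord <- integer(0)
  used <- integer(n)
  draw_elem <- function(min_val = 1L) {
    repeat {
      e <- names(params$alphabet)[sample.int(length(params$alphabet), 1L,
                                             prob = params$alphabet)]
      if (.max_valence[[e]] >= min_val) return(e)
    }
  }
  el[1] <- draw_elem()
  tip <- 1L
  for (i in seq_len(n)[-1]) {
    elig <- which(.max_valence[el[seq_len(i - 1L)]] - used[seq_len(i - 1L)] >= 1L)
    if (!length(elig)) { n <- i - 1L; break }
    parent <- if (tip %in% elig && stats::runif(1) >= params$branch_prob)
      tip else elig[sample.int(length(elig), 1L)]
    o <- 1L
    if (stats::runif(1) < params$double_bond_prob &&
        .max_valence[el[parent]] - used[parent] >= 2L) o <- 2L
    el[i] <- draw_elem(min_val = o)
    from <- c(from, parent); to <- c(to, i); ord <- c(ord, o)
    used[parent] <- used[parent] + o; used[i] <- used[i] + o
    tip <- i
  }
  el <- el[seq_len(n)]; used <- used[seq_len(n)]

  # ring closures between spare-valence atoms at tree distance 2..6
  if (n >= 3L) {
    d <- graph_distances(n, from, to)
    for (attempt in seq_len(max(1L, n %/% 8L))) {
      if (stats::runif(1) >= params$ring_prob) next
      cand <- which(.max_valence[el] - used >= 1L)
      if (length(cand) < 2L) next
      a <- cand[sample.int(length(cand), 1L)]
      b_ok <- cand[d[a, cand] >= 2L & d[a, cand] <= 6L]
      if (!length(b_ok)) next
      b <- b_ok[sample.int(length(b_ok), 1L)]
      from <- c(from, a); to <- c(to, b); ord <- c(ord, 1L)
      used[a] <- used[a] + 1L; used[b] <- used[b] + 1L
      d <- graph_distances(n, from, to)
    }
  }
  list(el = el, from = from, to = to, ord = ord, used = used)
}

graph_distances <- function(n, from, to) {
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (r in seq_along(from)) { d[from[r], to[r]] <- 1; d[to[r], from[r]] <- 1 }
  for (k in seq_len(n)) {
    dk <- d[, k]
    d <- pmin(d, outer(dk, d[k, ], `+`))
  }
  d
}

# Serialize a graph to SMILES by DFS (organic-subset elements only, so no
# brackets are needed).
graph_to_smiles <- function(g) {
  n <- length(g$el)
  adj <- vector("list", n)
  for (r in seq_along(g$from)) {
    adj[[g$from[r]]] <- rbind(adj[[g$from[r]]], c(g$to[r], g$ord[r]))
    adj[[g$to[r]]] <- rbind(adj[[g$to[r]]], c(g$from[r], g$ord[r]))
  }
  visited <- rep(FALSE, n)
  ring_at <- vector("list", n)  # vertex -> list of c(digit, order, first)
  next_digit <- 0L
  edge_seen <- new.env(hash = TRUE)
  ek <- function(a, b) paste0(min(a, b), "_", max(a, b))
  bond_sym <- function(o) c("", "=", "#")[o]

  # pre-walk to assign ring-closure digits deterministically
  assign_rings <- function(v, parent) {
    visited[v] <<- TRUE
    if (!is.null(adj[[v]])) for (r in seq_len(nrow(adj[[v]]))) {
      u <- adj[[v]][r, 1]; o <- adj[[v]][r, 2]
      key <- ek(v, u)
      if (u == parent && is.null(edge_seen[[key]])) { edge_seen[[key]] <- TRUE; next }
      if (!is.null(edge_seen[[key]])) next
      if (visited[u]) {
        edge_seen[[key]] <- TRUE
        next_digit <<- next_digit + 1L
        if (next_digit > 9L) stop("too many rings for single-digit labels")
        ring_at[[u]] <<- c(ring_at[[u]], list(c(next_digit, o, 1L)))
        ring_at[[v]] <<- c(ring_at[[v]], list(c(next_digit, o, 0L)))
      } else {
        edge_seen[[key]] <- TRUE
        assign_rings(u, v)
      }
    }
  }
  assign_rings(1L, 0L)

  visited <- rep(FALSE, n)
  write_atom <- function(v, parent, in_order) {
    visited[v] <<- TRUE
    s <- paste0(bond_sym(in_order), g$el[v])
    if (!is.null(ring_at[[v]])) for (rc in ring_at[[v]])
      s <- paste0(s, if (rc[3] == 1L) bond_sym(rc[2]) else "", rc[1])
    kids <- NULL
    if (!is.null(adj[[v]])) for (r in seq_len(nrow(adj[[v]]))) {
      u <- adj[[v]][r, 1]
      if (!visited[u]) kids <- rbind(kids, adj[[v]][r, ])
    }
    if (!is.null(kids)) {
      nk <- nrow(kids)
      for (r in seq_len(nk)) {
        u <- kids[r, 1]
        if (visited[u]) next  # may have been reached via a ring path
        sub <- write_atom(u, v, kids[r, 2])
        more <- r < nk && any(!visited[kids[seq(r + 1L, nk), 1]])
        s <- if (more) paste0(s, "(", sub, ")") else paste0(s, sub)
      }
    }
    s
  }
  write_atom(1L, 0L, 0L)
}

#' Generate one random molecule
#'
#' Assembles a random valence-respecting tree with optional rings and double
#' bonds, and serializes it to a valid SMILES string.
#'
#' @param params a [scfp_gen_params()].
#' @param seed optional seed (otherwise the current RNG state is used).
#' @return a SMILES string.
#' @export
generate_molecule <- function(params = scfp_gen_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  graph_to_smiles(random_graph(params))
}

# attach the fragment graph to a random scaffold atom with spare valence
plant_fragment <- function(g, frag) {
  host <- which(.max_valence[g$el] - g$used >= 1L)
  if (!length(host)) return(NULL)
  pref <- host[g$el[host] == "C"]
  a <- if (length(pref)) pref[sample.int(length(pref), 1L)]
       else host[sample.int(length(host), 1L)]
  off <- length(g$el)
  g$el <- c(g$el, frag$el)
  g$from <- c(g$from, a, frag$from + off)
  g$to <- c(g$to, off + 1L, frag$to + off)
  g$ord <- c(g$ord, 1L, frag$ord)
  g$used[a] <- g$used[a] + 1L
  g$used <- c(g$used, frag$used)
  g$used[off + 1L] <- g$used[off + 1L] + 1L
  g
}

# fragment SMILES -> generator graph (raw parse, no toolkit round trip)
fragment_graph <- function(smiles) {
  tk <- tokenize_smiles(smiles)
  mol <- build_graph(tk)
  used <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds)) for (r in seq_len(nrow(mol$bonds))) {
    used[mol$bonds$from[r]] <- used[mol$bonds$from[r]] + mol$bonds$order[r]
    used[mol$bonds$to[r]] <- used[mol$bonds$to[r]] + mol$bonds$order[r]
  }
  list(el = mol$atoms$element, from = mol$bonds$from, to = mol$bonds$to,
       ord = as.integer(mol$bonds$order), used = as.integer(used))
}

mol_to_igraph <- function(el, from, to, ord) {
  g <- igraph::make_empty_graph(n = length(el), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  igraph::V(g)$color <- match(el, c("H", names(.max_valence)))
  igraph::E(g)$color <- as.integer(round(ord))
  g
}

#' Find a substructure in a molecule
#'
#' Subgraph monomorphism with element and bond-order matching (VF2).
#'
#' @param mol an `scfp_molecule`.
#' @param fragment_smiles fragment as SMILES; first atom onward, all atoms
#'   and bonds must be present with matching elements and bond orders.
#' @return list of integer vectors: atom ordinals (in `mol`) of each match.
#' @export
match_substructure <- function(mol, fragment_smiles) {
  frag <- fragment_graph(fragment_smiles)
  gt <- mol_to_igraph(mol$atoms$element, mol$bonds$from, mol$bonds$to,
                      mol$bonds$order)
  gp <- mol_to_igraph(frag$el, frag$from, frag$to, frag$ord)
  ms <- igraph::subgraph_isomorphisms(gp, gt, method = "vf2")
  unique(lapply(ms, function(m) sort(as.integer(m))))
}

#' Generate a labeled dataset with a planted substructure
#'
#' Active compounds carry at least one embedded copy of `planted_motif`
#' (attached at a random scaffold atom); inactive compounds are verified by
#' substructure search NOT to contain it (rejection sampling).  Ground-truth
#' motif atom ordinals are recomputed on the canonical SMILES by substructure
#' matching, since canonicalization reorders atoms.
#'
#' @param params a [scfp_gen_params()].
#' @param max_tries rejection-sampling bound per compound.
#' @return data frame with columns `id`, `smiles` (canonical), `label`, and a
#'   list column `motif_atoms` (for actives: atom ordinals of each planted /
#'   incidental match; empty for inactives).
#' @export
generate_planted_dataset <- function(params = scfp_gen_params(),
                                     max_tries = 200L) {
  set.seed(params$seed)
  frag <- fragment_graph(params$planted_motif)
  n <- params$n_active + params$n_inactive
  label <- rep(c(1L, 0L), c(params$n_active, params$n_inactive))
  raw <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      g <- random_graph(params)
      if (label[i] == 1L) {
        g <- plant_fragment(g, frag)
        if (is.null(g)) next
      } else {
        mol <- list(atoms = data.frame(element = g$el),
                    bonds = data.frame(from = g$from, to = g$to,
                                       order = g$ord))
        if (length(match_substructure(mol, params$planted_motif))) next
      }
      raw[i] <- graph_to_smiles(g)
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not generate a compound with label ", label[i],
           " in ", max_tries, " tries (fragment '", params$planted_motif,
           "' too ", if (label[i] == 1L) "hard to place" else "ubiquitous",
           ")", call. = FALSE)
  }
  can <- canonicalize_smiles(raw)
  motif_atoms <- vector("list", n)
  for (i in seq_len(n)) {
    mol <- smiles_molecule(can[i], canonical = TRUE,
                           perceive_aromaticity = FALSE)
    hits <- match_substructure(mol, params$planted_motif)
    if (label[i] == 1L && !length(hits))
      stop("planted fragment lost during canonicalization for compound ", i,
           call. = FALSE)
    if (label[i] == 0L && length(hits))
      stop("rejection sampling failed: inactive compound ", i,
           " contains the fragment", call. = FALSE)
    motif_atoms[[i]] <- hits
  }
  out <- data.frame(id = sprintf("cmpd%04d", seq_len(n)),
                    smiles = can, label = label,
                    stringsAsFactors = FALSE)
  out$motif_atoms <- motif_atoms
  out
}
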