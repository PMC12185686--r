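# Canonical SMILES writer. Canonical ranks come from iterative neighbour
# refinement over an initial atom invariant (Morgan-style), with
# deterministic tie-breaking by rank promotion. The writer emits lowercase
# atoms and default bonds inside perceived aromatic systems, bracket atoms
# whenever charge/isotope/non-standard H force one, and ring-closure
# digits. Canonical means: two parses of any SMILES of the same labelled
# graph produce the same string (given the same aromatic flags).

canonical_ranks <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return(integer())
  adj <- mol_adj(mol)
  deg <- vapply(adj, function(a) length(a$nbr), 0L)
  inv0 <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$isotope,
                mol$atoms$aromatic, mol$atoms$nH, deg, sep = "|")
  rank <- as.integer(factor(inv0, levels = sort(unique(inv0))))
  refine <- function(rank) {
    repeat {
      key <- character(n)
      for (i in seq_len(n)) {
        # zero-padded ranks so lexicographic level sort equals numeric sort
        nb <- sort(sprintf("%05d", rank[adj[[i]]$nbr]))
        bo <- sort(paste0(mol$bonds$order[adj[[i]]$bond],
                          ifelse(mol$bonds$aromatic[adj[[i]]$bond], "a", "")))
        key[i] <- paste(sprintf("%05d", rank[i]), paste(nb, collapse = ","),
                        paste(bo, collapse = ","), sep = ";")
      }
      new_rank <- as.integer(factor(key, levels = sort(unique(key))))
      if (identical(new_rank, rank)) return(rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  # tie-break: promote the lowest-index atom of the lowest tied rank
  while (length(unique(rank)) < n) {
    tab <- table(rank)
    tied <- as.integer(names(tab)[tab > 1])
    r <- min(tied)
    i <- which(rank == r)[1]
    rank <- rank + as.integer(rank > r | (rank == r & seq_len(n) != i))
    rank[i] <- r
    rank <- refine(rank)
  }
  rank
}

smiles_atom_token <- function(mol, i) {
  el <- mol$atoms$element[i]
  arom <- mol$atoms$aromatic[i]
  chg <- mol$atoms$charge[i]
  iso <- mol$atoms$isotope[i]
  nH <- mol$atoms$nH[i]
  sym <- if (arom) tolower(el) else el
  organic <- el %in% names(.ORGANIC_VALENCE) || el == "*"
  # does the implicit-H convention reproduce nH without a bracket?
  needs_bracket <- chg != 0L || iso != 0L || !organic
  if (!needs_bracket && el != "*") {
    b <- mol$bonds
    bos <- 0
    for (k in seq_len(nrow(b))) {
      if (b$a1[k] != i && b$a2[k] != i) next
      bos <- bos + (if (b$aromatic[k]) 1.5 else b$order[k])
    }
    default_h <- max(0L, as.integer(.ORGANIC_VALENCE[el]) -
                       as.integer(ceiling(bos)))
    if (default_h != nH) needs_bracket <- TRUE
  }
  if (!needs_bracket) return(sym)
  paste0("[",
         if (iso != 0L) iso else "",
         sym,
         if (nH == 1L) "H" else if (nH > 1L) paste0("H", nH) else "",
         if (chg == 1L) "+" else if (chg > 1L) paste0("+", chg)
         else if (chg == -1L) "-" else if (chg < -1L) chg else "",
         "]")
}

bond_token <- function(mol, k, from, to) {
  if (mol$bonds$aromatic[k]) {
    if (mol$atoms$aromatic[from] && mol$atoms$aromatic[to]) return("")
    return(":")
  }
  o <- mol$bonds$order[k]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  # single bond between two aromatic atoms must be written explicitly
  if (mol$atoms$aromatic[from] && mol$atoms$aromatic[to]) return("-")
  ""
}

#' Write a canonical SMILES string
#'
#' @param mol an `ss_mol`.
#' @return A single SMILES string; identical for any atom ordering of the
#'   same labelled graph (with the same aromatic flags).
#' @export
#' @examples
#' write_smiles(parse_smiles("OCC")) == write_smiles(parse_smiles("CCO"))
write_smiles <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) return("")
  rank <- canonical_ranks(mol)
  adj <- mol_adj(mol)
  comp <- mol_components(mol)
  visited <- logical(n)
  bond_used <- logical(n_bonds(mol))
  ring_digit <- 0L
  closure_tok <- vector("list", n)   # per-atom ring-closure tokens, in order
  children <- vector("list", n)      # per-atom list(atom, bond) tree children
  for (i in seq_len(n)) { closure_tok[[i]] <- character(); children[[i]] <- list() }
  # pass 1: DFS in canonical order; classify tree edges and back edges,
  # assigning ring-closure digits to both endpoints up front
  plan <- function(i) {
    visited[i] <<- TRUE
    nbrs <- adj[[i]]$nbr; bks <- adj[[i]]$bond
    ord <- order(rank[nbrs])
    nbrs <- nbrs[ord]; bks <- bks[ord]
    for (t in seq_along(nbrs)) {
      k <- bks[t]
      if (bond_used[k]) next
      j <- nbrs[t]
      if (visited[j]) {
        bond_used[k] <<- TRUE
        ring_digit <<- ring_digit + 1L
        d <- if (ring_digit > 9L) paste0("%", ring_digit)
             else as.character(ring_digit)
        tok <- paste0(bond_token(mol, k, i, j), d)
        closure_tok[[i]] <<- c(closure_tok[[i]], tok)
        closure_tok[[j]] <<- c(closure_tok[[j]], tok)
      } else {
        bond_used[k] <<- TRUE
        children[[i]] <<- c(children[[i]], list(list(atom = j, bond = k)))
        plan(j)
      }
    }
  }
  # pass 2: render from the recorded tree
  render <- function(i) {
    token <- paste0(smiles_atom_token(mol, i),
                    paste(closure_tok[[i]], collapse = ""))
    ch <- children[[i]]
    if (!length(ch)) return(token)
    parts <- token
    for (t in seq_along(ch)) {
      sub <- paste0(bond_token(mol, ch[[t]]$bond, i, ch[[t]]$atom),
                    render(ch[[t]]$atom))
      if (t < length(ch)) sub <- paste0("(", sub, ")")
      parts <- c(parts, sub)
    }
    paste(parts, collapse = "")
  }
  pieces <- character()
  for (cid in sort(unique(comp))) {
    members <- which(comp == cid)
    root <- members[which.min(rank[members])]
    plan(root)
    pieces <- c(pieces, render(root))
  }
  paste(pieces, collapse = ".")
}

#' Canonical SMILES of a SMILES string
#'
#' Convenience round-trip used throughout the test-suite and the membership
#' machinery: parse, then write canonically. Aromatic flags are taken from
#' the input (lowercase) SMILES; use [perceive_aromaticity()] to impose a
#' model first when comparing across sources.
#'
#' @param smiles a SMILES string.
#' @param model optional aromaticity model to re-perceive under before
#'   writing (`NULL` keeps parsed flags).
#' @return Canonical SMILES string.
#' @export
canonical_smiles <- function(smiles, model = NULL) {
  mol <- parse_smiles(smiles)
  if (!is.null(model)) mol <- perceive_aromaticity(mol, model)
  write_smiles(mol)
}
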