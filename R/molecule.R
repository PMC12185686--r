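# The molecule container: a plain molecular graph with per-atom
# element/charge/isotope-label/aromatic-flag/implicit-H fields and per-bond
# order/aromatic/ring fields. Explicit hydrogens are folded into `nH` at
# parse time; ring flags are perceived lazily.

#' Construct a molecule object
#'
#' Low-level constructor used by the SMILES reader and the fixture
#' generator. Most users obtain molecules from [parse_smiles()] or
#' [read_building_blocks()].
#'
#' @param atoms data frame with columns `element` (character), `charge`
#'   (integer), `isotope` (integer, 0 = unlabelled; also carries synthon
#'   map labels), `aromatic` (logical), `nH` (integer implicit hydrogens).
#' @param bonds data frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2 or 3), `aromatic` (logical), `ring` (logical).
#' @param name molecule name.
#' @param source_id identifier carried from the input file.
#' @return An object of class `ss_mol`.
#' @export
new_mol <- function(atoms, bonds, name = "", source_id = "") {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  structure(list(atoms = atoms, bonds = bonds,
                 name = name, source_id = source_id),
            class = "ss_mol")
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = integer(),
             aromatic = logical(), ring = logical())
}

n_atoms <- function(mol) nrow(mol$atoms)
n_bonds <- function(mol) nrow(mol$bonds)

#' @export
print.ss_mol <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, %d bonds%s>\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              n_atoms(x), n_bonds(x),
              if (nzchar(x$source_id)) paste0(", id=", x$source_id) else ""))
  invisible(x)
}

# Adjacency: list over atoms, each element a list(nbr = int vector of
# neighbour atoms, bond = int vector of bond indices, parallel).
mol_adj <- function(mol) {
  nb <- vector("list", n_atoms(mol))
  for (i in seq_along(nb)) nb[[i]] <- list(nbr = integer(), bond = integer())
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    nb[[i]]$nbr <- c(nb[[i]]$nbr, j); nb[[i]]$bond <- c(nb[[i]]$bond, k)
    nb[[j]]$nbr <- c(nb[[j]]$nbr, i); nb[[j]]$bond <- c(nb[[j]]$bond, k)
  }
  nb
}

# Connected components as a vector of component ids (1-based).
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  adj <- mol_adj(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]$nbr) {
        if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# Smallest-ring set: for every bond, the shortest cycle through it (BFS with
# the bond removed). Returns a list of integer atom-index vectors (each a
# cycle, deduplicated) and marks ring flags on bonds. Adequate for the small
# fused systems the transform corpus touches; not a full SSSR algorithm.
perceive_rings <- function(mol, max_ring = 12L) {
  n <- n_atoms(mol)
  adj <- mol_adj(mol)
  rings <- list()
  seen <- character()
  nb <- nrow(mol$bonds)
  ring_bond <- logical(nb)
  for (k in seq_len(nb)) {
    src <- mol$bonds$a1[k]; dst <- mol$bonds$a2[k]
    # BFS from dst to src avoiding bond k
    prev <- integer(n); prev[] <- NA_integer_
    dist <- rep(Inf, n)
    dist[dst] <- 0
    queue <- dst
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (v == src) break
      a <- adj[[v]]
      for (t in seq_along(a$nbr)) {
        if (a$bond[t] == k) next
        w <- a$nbr[t]
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.infinite(dist[src]) || dist[src] + 1 > max_ring) next
    path <- src
    v <- src
    while (v != dst) { v <- prev[v]; path <- c(path, v) }
    key <- paste(sort(path), collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  # ring bond flags: bond lies on some stored cycle
  if (length(rings)) {
    ring_edges <- character()
    for (r in rings) {
      cyc <- c(r, r[1])
      for (t in seq_len(length(r))) {
        e <- sort(c(cyc[t], cyc[t + 1]))
        ring_edges <- c(ring_edges, paste(e, collapse = "-"))
      }
    }
    keys <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                  pmax(mol$bonds$a1, mol$bonds$a2), sep = "-")
    ring_bond <- keys %in% ring_edges
  }
  list(rings = rings, ring_bond = ring_bond)
}

# Attach ring info to the molecule (bond$ring flags and a cached ring list).
with_rings <- function(mol) {
  ri <- perceive_rings(mol)
  mol$bonds$ring <- ri$ring_bond
  attr(mol, "rings") <- ri$rings
  mol
}

mol_rings <- function(mol) {
  r <- attr(mol, "rings")
  if (is.null(r)) {
    mol <- with_rings(mol)
    r <- attr(mol, "rings")
  }
  r
}

# Number of distinct smallest rings through each atom (SMARTS R primitive).
atom_ring_counts <- function(mol) {
  rings <- mol_rings(mol)
  cnt <- integer(n_atoms(mol))
  for (r in rings) cnt[r] <- cnt[r] + 1L
  cnt
}

# Bonds shared by two or more smallest rings (true fusion bonds).
fusion_bonds <- function(mol) {
  rings <- mol_rings(mol)
  keys <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                pmax(mol$bonds$a1, mol$bonds$a2), sep = "-")
  cnt <- integer(nrow(mol$bonds))
  for (r in rings) {
    cyc <- c(r, r[1])
    for (t in seq_len(length(r))) {
      e <- paste(min(cyc[t], cyc[t + 1]), max(cyc[t], cyc[t + 1]), sep = "-")
      cnt[keys == e] <- cnt[keys == e] + 1L
    }
  }
  which(cnt >= 2L)
}

# Total bond order of each atom including implicit H; aromatic bonds use
# their kekulized order (molecules are kekulized on parse).
atom_total_order <- function(mol) {
  tot <- mol$atoms$nH
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    tot[b$a1[k]] <- tot[b$a1[k]] + b$order[k]
    tot[b$a2[k]] <- tot[b$a2[k]] + b$order[k]
  }
  tot
}

#' Molecular weight
#'
#' Average molecular weight of a molecule from the bundled standard atomic
#' weights, including implicit hydrogens. Dummy (link) atoms weigh zero, so
#' synthon fragment masses are additive across a formed bond.
#'
#' @param mol an `ss_mol`.
#' @return Mass in g/mol.
#' @export
#' @examples
#' mol_mw(parse_smiles("CC(=O)O")) # acetic acid, ~60.05
mol_mw <- function(mol) {
  if (n_atoms(mol) == 0L) return(0)
  sum(element_mass(mol$atoms$element)) +
    sum(mol$atoms$nH) * element_mass("H")
}

heavy_atom_count <- function(mol) sum(mol$atoms$element != "H")

# Extract the sub-molecule induced by `keep` (integer atom indices).
mol_subset <- function(mol, keep) {
  keep <- sort(unique(keep))
  idx_map <- integer(n_atoms(mol))
  idx_map[keep] <- seq_along(keep)
  b <- mol$bonds
  sel <- b$a1 %in% keep & b$a2 %in% keep
  b <- b[sel, , drop = FALSE]
  b$a1 <- idx_map[b$a1]; b$a2 <- idx_map[b$a2]
  rownames(b) <- NULL
  a <- mol$atoms[keep, , drop = FALSE]
  rownames(a) <- NULL
  new_mol(a, b, name = mol$name, source_id = mol$source_id)
}

# Delete the listed atoms (their bonds go with them).
mol_delete_atoms <- function(mol, drop) {
  mol_subset(mol, setdiff(seq_len(n_atoms(mol)), drop))
}

bond_between <- function(mol, i, j) {
  b <- mol$bonds
  which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
}
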