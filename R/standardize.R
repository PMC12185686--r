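# Building-block standardization and the valence/protecting-group checks
# applied before any pattern matching.

#' Standardize a building block
#'
#' Applies the building-block cleanup pipeline: strips disconnected
#' metal/salt components (keeping the largest organic component),
#' neutralizes charge-separated sulfoxides (S+–O- to S=O), protonates
#' carboxylates, rejects organometallics (any carbon–metal bond against a
#' configurable metal set) and rejects molecules above the molecular
#' weight cap. Explicit hydrogens are already folded into implicit counts
#' at parse time. The weight is measured on the desalted, still-protected
#' structure; the cutoff is strict (`> mw_cap` rejects, `= mw_cap` is
#' kept).
#'
#' @param mol an `ss_mol`.
#' @param mw_cap molecular weight cap in g/mol (default 700).
#' @param metal_set character vector of element symbols counted as metals.
#' @return The standardized `ss_mol`, or an object of class
#'   `ss_rejection` with a `reason` field (`"organometallic"` or
#'   `"overweight"`).
#' @export
#' @examples
#' write_smiles(standardize(parse_smiles("CC(=O)[O-].[Na+]")))  # "C(C)(O)=O"
standardize <- function(mol, mw_cap = 700, metal_set = .DEFAULT_METAL_SET) {
  # organometallic: carbon-metal bond anywhere in the input
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    e1 <- mol$atoms$element[b$a1[k]]; e2 <- mol$atoms$element[b$a2[k]]
    if ((e1 == "C" && is_metal(e2, metal_set)) ||
        (e2 == "C" && is_metal(e1, metal_set))) {
      return(rejection(mol, "organometallic"))
    }
  }
  # salt stripping: drop components without carbon or made of metals only;
  # keep the largest surviving organic component
  comp <- mol_components(mol)
  organic <- integer()
  best_size <- -1L
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    els <- mol$atoms$element[members]
    if (!any(els == "C")) next
    if (all(is_metal(els, metal_set))) next
    if (length(members) > best_size) { best_size <- length(members); organic <- members }
  }
  if (!length(organic)) return(rejection(mol, "organometallic"))
  mol <- mol_subset(mol, organic)
  mol <- neutralize_sulfoxides(mol)
  mol <- protonate_carboxylates(mol)
  mol <- with_rings(mol)
  if (mol_mw(mol) > mw_cap) return(rejection(mol, "overweight"))
  mol
}

rejection <- function(mol, reason) {
  structure(list(source_id = mol$source_id, name = mol$name, reason = reason),
            class = "ss_rejection")
}

#' @export
print.ss_rejection <- function(x, ...) {
  cat(sprintf("<rejected %s: %s>\n",
              if (nzchar(x$source_id)) x$source_id else x$name, x$reason))
  invisible(x)
}

is_rejection <- function(x) inherits(x, "ss_rejection")

neutralize_sulfoxides <- function(mol) {
  repeat {
    hit <- smarts_match(mol, "[S+][O-]")
    if (!length(hit)) return(mol)
    s <- hit[[1]][1]; o <- hit[[1]][2]
    k <- bond_between(mol, s, o)
    mol$bonds$order[k] <- 2L
    mol$atoms$charge[c(s, o)] <- 0L
  }
}

protonate_carboxylates <- function(mol) {
  repeat {
    hit <- smarts_match(mol, "[O;-;X1][CX3]=[OX1]")
    if (!length(hit)) return(mol)
    o <- hit[[1]][1]
    mol$atoms$charge[o] <- 0L
    mol$atoms$nH[o] <- mol$atoms$nH[o] + 1L
  }
}

#' Check valence states
#'
#' `FALSE` when any atom's (element, charge, total bond order incl.
#' implicit H) triple is absent from the allowed-valence table — e.g. a
#' pentavalent carbon or an uncharged tetravalent nitrogen, the
#' non-favored states the valence model forbids.
#'
#' @param mol an `ss_mol` (kekulized orders are used for aromatic bonds).
#' @param valence_table allowed (element, charge, order) data frame; see
#'   [default_valence_table()].
#' @return `TRUE` if every atom is in an allowed valence state.
#' @export
#' @examples
#' check_valence(parse_smiles("C"))          # TRUE
#' check_valence(parse_smiles("CN(C)(C)C"))  # FALSE: uncharged N(IV)
check_valence <- function(mol, valence_table = default_valence_table()) {
  tot <- atom_total_order(mol)
  key <- paste(valence_table$element, valence_table$charge,
               valence_table$order)
  for (i in seq_len(n_atoms(mol))) {
    k <- paste(mol$atoms$element[i], mol$atoms$charge[i], tot[i])
    if (!(k %in% key)) return(FALSE)
  }
  TRUE
}

.pg_cache <- new.env(parent = emptyenv())

protecting_group_table <- function() {
  if (is.null(.pg_cache$groups)) {
    path <- system.file("extdata", "protecting_groups.json",
                        package = "synthonspace", mustWork = FALSE)
    if (!nzchar(path) || !file.exists(path)) {
      # fallback for source() use during development
      path <- file.path("inst", "extdata", "protecting_groups.json")
    }
    dat <- jsonlite::read_json(path, simplifyVector = FALSE)
    .pg_cache$groups <- lapply(dat$groups, function(g) {
      list(name = g$name, class = g$class,
           pattern = parse_smarts(g$smarts),
           delete = unlist(g$delete), add_h = g$add_h)
    })
  }
  .pg_cache$groups
}

#' Remove protecting groups
#'
#' Strips the seven bundled groups — Boc, Fmoc and Cbz from amines,
#' tert-butyl and benzyl esters from carboxyls, tert-butyl ethers and
#' benzoates from hydroxyls — restoring the free amine/acid/alcohol.
#' Removal re-scans until no group matches, so stacked or repeated
#' protections all come off.
#'
#' @param mol an `ss_mol` with aromaticity perceived (the group patterns
#'   contain aromatic rings).
#' @return A list with `mol` (deprotected molecule) and `removed`
#'   (character vector of group names, one entry per removal).
#' @export
#' @examples
#' r <- remove_protecting_groups(
#'   perceive_aromaticity(parse_smiles("CC(C)(C)OC(=O)NCC(=O)O"), "DEFAULT"))
#' r$removed                 # "Boc"
#' write_smiles(r$mol)       # glycine
remove_protecting_groups <- function(mol) {
  groups <- protecting_group_table()
  removed <- character()
  repeat {
    hit_any <- FALSE
    for (g in groups) {
      m <- smarts_match(mol, g$pattern)
      if (!length(m)) next
      hit <- m[[1]]
      keep_atom <- hit[1]
      mol$atoms$nH[keep_atom] <- mol$atoms$nH[keep_atom] + g$add_h
      mol <- mol_delete_atoms(mol, hit[g$delete])
      removed <- c(removed, g$name)
      hit_any <- TRUE
      break
    }
    if (!hit_any) break
    if (length(removed) > 50L) stop("protecting-group removal did not converge")
  }
  mol <- with_rings(mol)
  list(mol = mol, removed = removed)
}
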