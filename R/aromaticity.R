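# Switchable aromaticity perception.
#
# Two models are supported, selected per pipeline run:
#
# * DEFAULT — an electron-counting model in the spirit of NAOMI/RDKit:
#   a ring is aromatic if every member is sp2-capable and the Hückel count
#   is 4n+2. Ring atoms carrying an exocyclic double bond stay
#   aromatic-capable (contributing no pi electron) when the exocyclic
#   partner is O, N or S (2-pyridone stays aromatic); an exocyclic double
#   bond to carbon breaks aromaticity (fulvene-like systems).
# * CACTVS — any exocyclic double bond on a ring atom renders that ring
#   non-aromatic regardless of the partner element; the ring keeps its
#   alternating Kekulé single/double orders, so valence states stay
#   correct.
#
# Perception operates on the kekulized structure, so flipping the model
# never changes connectivity or hydrogen counts, only aromatic flags.

#' Aromaticity models
#'
#' @return Character vector of the supported model names.
#' @export
aromaticity_models <- function() c("DEFAULT", "CACTVS")

#' Perceive aromaticity under a chosen model
#'
#' Resets all aromatic flags from the Kekulé structure under either the
#' `"DEFAULT"` (electron counting; exocyclic double bonds to O/N/S keep the
#' ring aromatic) or the `"CACTVS"` model (any exocyclic double bond makes
#' the ring non-aromatic, its bonds stay alternating single/double).
#'
#' @param mol an `ss_mol` (kekulized, as produced by [parse_smiles()]).
#' @param model `"DEFAULT"` or `"CACTVS"`.
#' @return The molecule with aromatic flags set per the model.
#' @export
#' @examples
#' m <- parse_smiles("O=c1cccc[nH]1")              # 2-pyridone
#' any(perceive_aromaticity(m, "DEFAULT")$atoms$aromatic)  # TRUE
#' any(perceive_aromaticity(m, "CACTVS")$atoms$aromatic)   # FALSE
perceive_aromaticity <- function(mol, model = c("DEFAULT", "CACTVS")) {
  model <- match.arg(model)
  mol <- with_rings(mol)
  rings <- mol_rings(mol)
  mol$atoms$aromatic <- rep(FALSE, n_atoms(mol))
  mol$bonds$aromatic <- rep(FALSE, n_bonds(mol))
  if (!length(rings)) return(mol)
  b <- mol$bonds
  n <- n_atoms(mol)
  # per-atom: double bond to a ring atom / exocyclic double partner element
  endo_double <- logical(n)      # double bond to another atom in any ring
  exo_double_to <- rep(NA_character_, n)
  in_ring <- logical(n)
  for (r in rings) in_ring[r] <- TRUE
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 2L) next
    i <- b$a1[k]; j <- b$a2[k]
    if (b$ring[k]) { endo_double[i] <- TRUE; endo_double[j] <- TRUE }
    else {
      if (in_ring[i]) exo_double_to[i] <- mol$atoms$element[j]
      if (in_ring[j]) exo_double_to[j] <- mol$atoms$element[i]
    }
  }
  deg <- integer(n)
  for (k in seq_len(nrow(b))) {
    deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    deg[b$a2[k]] <- deg[b$a2[k]] + 1L
  }
  arom_atoms <- logical(n)
  arom_ring <- logical(length(rings))
  for (ri in seq_along(rings)) {
    r <- rings[[ri]]
    if (length(r) < 5L || length(r) > 7L) next
    pi <- 0L
    ok <- TRUE
    for (i in r) {
      el <- mol$atoms$element[i]
      exo <- exo_double_to[i]
      if (!is.na(exo)) {
        if (model == "CACTVS") { ok <- FALSE; break }
        if (!(exo %in% c("O", "N", "S"))) { ok <- FALSE; break }
        # sp2, contributes no pi electron (carbonyl-type carbon)
        contrib <- 0L
      } else if (endo_double[i]) {
        contrib <- 1L
      } else if (el %in% c("N", "P") && mol$atoms$charge[i] == 0L) {
        contrib <- 2L  # pyrrole-type lone pair
      } else if (el %in% c("O", "S") && mol$atoms$charge[i] == 0L) {
        contrib <- 2L  # furan/thiophene oxygen/sulfur
      } else if (el == "C" && mol$atoms$charge[i] == -1L) {
        contrib <- 2L  # cyclopentadienyl
      } else { ok <- FALSE; break }
      pi <- pi + contrib
    }
    if (ok && (pi - 2L) %% 4L == 0L && pi >= 6L) {
      arom_ring[ri] <- TRUE
      arom_atoms[r] <- TRUE
    }
  }
  mol$atoms$aromatic <- arom_atoms
  # a bond is aromatic when it lies in an aromatic perceived ring
  for (ri in which(arom_ring)) {
    r <- rings[[ri]]
    cyc <- c(r, r[1])
    for (t in seq_len(length(r))) {
      kb <- bond_between(mol, cyc[t], cyc[t + 1])
      mol$bonds$aromatic[kb] <- TRUE
    }
  }
  attr(mol, "aromaticity_model") <- model
  mol
}
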