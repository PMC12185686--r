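# SMILES reader. Covers the subset the pipeline needs: organic-subset and
# bracket atoms, charges, isotopes (which double as synthon map labels),
# explicit H counts, bonds - = # : ~, branches, ring-closure digits and
# %nn pairs, dot-separated components, and aromatic (lowercase) input with
# kekulization. Stereo descriptors are accepted and discarded (out of
# scope). Explicit [H] atoms are folded into the neighbour's nH.

.ORGANIC_TOKENS <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I",
                     "b", "c", "n", "o", "p", "s", "*")

#' Parse a SMILES string
#'
#' @param smiles a single SMILES string.
#' @param name,source_id metadata carried on the molecule.
#' @param kekulize if `TRUE` (default), aromatic input is converted to a
#'   Kekulé structure (alternating single/double orders) while keeping
#'   aromatic flags; fails if no consistent assignment exists.
#' @return An `ss_mol`.
#' @export
#' @examples
#' parse_smiles("c1ccccc1O") # phenol
parse_smiles <- function(smiles, name = "", source_id = "", kekulize = TRUE) {
  s <- gsub("[[:space:]]", "", smiles)
  if (!nzchar(s)) stop("empty SMILES")
  atoms <- list(); abonds <- list()
  pos <- 1L; nchr <- nchar(s)
  prev <- 0L                       # previous atom index (0 = none)
  pending_bond <- NA_character_    # bond symbol waiting for next atom
  stack <- integer()               # branch stack
  ring_open <- list()              # closure digit -> list(atom, sym)
  add_atom <- function(element, charge = 0L, isotope = 0L, aromatic = FALSE,
                       nH = NA_integer_, explicit_h = FALSE) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, charge = charge,
      isotope = isotope, aromatic = aromatic, nH = nH, explicit_h = explicit_h)
    length(atoms)
  }
  add_bond <- function(i, j, sym) {
    abonds[[length(abonds) + 1L]] <<- list(a1 = i, a2 = j, sym = sym)
  }
  connect <- function(idx) {
    if (prev > 0L) add_bond(prev, idx, pending_bond)
    prev <<- idx
    pending_bond <<- NA_character_
  }
  while (pos <= nchr) {
    ch <- substr(s, pos, pos)
    two <- substr(s, pos, pos + 1L)
    if (ch == "(") {
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES at position ", pos)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~", "/", "\\")) {
      pending_bond <- if (ch %in% c("/", "\\")) "-" else ch
      pos <- pos + 1L
    } else if (ch == ".") {
      prev <- 0L; pending_bond <- NA_character_; pos <- pos + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        digit <- substr(s, pos + 1L, pos + 2L); pos <- pos + 3L
      } else { digit <- ch; pos <- pos + 1L }
      if (prev == 0L) stop("ring closure before any atom in SMILES")
      key <- digit
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        sym <- if (!is.na(pending_bond)) pending_bond else op$sym
        add_bond(op$atom, prev, sym)
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, sym = pending_bond)
      }
      pending_bond <- NA_character_
    } else if (ch == "[") {
      close <- regexpr("]", substr(s, pos, nchr), fixed = TRUE)
      if (close < 0) stop("unterminated bracket atom in SMILES")
      body <- substr(s, pos + 1L, pos + close - 2L)
      pos <- pos + close
      at <- parse_bracket_atom(body)
      if (at$element == "H" && prev > 0L) {
        # explicit hydrogen: fold into the previous atom
        atoms[[prev]]$nH <- (if (is.na(atoms[[prev]]$nH)) 0L else atoms[[prev]]$nH) + 1L
        atoms[[prev]]$explicit_h <- TRUE
        pending_bond <- NA_character_
      } else {
        idx <- add_atom(at$element, at$charge, at$isotope, at$aromatic,
                        at$nH, explicit_h = TRUE)
        connect(idx)
      }
    } else if (two %in% .ORGANIC_TOKENS) {
      idx <- add_atom(two); connect(idx); pos <- pos + 2L
    } else if (ch %in% .ORGANIC_TOKENS) {
      aromatic <- ch %in% c("b", "c", "n", "o", "p", "s")
      el <- if (aromatic) toupper(ch) else ch
      idx <- add_atom(el, aromatic = aromatic); connect(idx)
      pos <- pos + 1L
    } else {
      stop("unexpected character '", ch, "' at position ", pos,
           " in SMILES: ", smiles)
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(ring_open) && any(!vapply(ring_open, is.null, TRUE)))
    stop("unclosed ring bond in SMILES: ", smiles)
  build_mol_from_parse(atoms, abonds, name, source_id, kekulize)
}

parse_bracket_atom <- function(body) {
  isotope <- 0L
  m <- regmatches(body, regexpr("^[0-9]+", body))
  if (length(m)) { isotope <- as.integer(m); body <- sub("^[0-9]+", "", body) }
  m <- regmatches(body, regexpr("^([A-Z][a-z]?|[bcnops]|\\*)", body))
  if (!length(m)) stop("cannot read element in bracket atom [", body, "]")
  sym <- m
  body <- sub("^([A-Z][a-z]?|[bcnops]|\\*)", "", body)
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
  element <- if (aromatic) toupper(sym) else sym
  body <- gsub("@|TH[12]", "", body)  # stereo ignored
  nH <- 0L
  m <- regmatches(body, regexpr("H[0-9]*", body))
  if (length(m)) {
    nH <- if (m == "H") 1L else as.integer(substring(m, 2L))
    body <- sub("H[0-9]*", "", body)
  }
  charge <- 0L
  m <- regmatches(body, regexpr("\\+\\+|--|\\+[0-9]*|-[0-9]*", body))
  if (length(m) && nzchar(m)) {
    charge <- switch(m, "++" = 2L, "--" = -2L, "+" = 1L, "-" = -1L,
                     as.integer(sub("\\+", "", m)) *
                       (if (startsWith(m, "-")) -1L else 1L))
    if (startsWith(m, "-") && !(m %in% c("-", "--")))
      charge <- -as.integer(substring(m, 2L))
    body <- sub("\\+\\+|--|\\+[0-9]*|-[0-9]*", "", body)
  }
  body <- sub("^:[0-9]+", "", body)  # atom map (ignored on molecules)
  if (nzchar(body)) stop("unparsed bracket atom remainder: '", body, "'")
  list(element = element, charge = charge, isotope = isotope,
       aromatic = aromatic, nH = nH)
}

build_mol_from_parse <- function(atoms, abonds, name, source_id, kekulize) {
  nat <- length(atoms)
  a <- data.frame(
    element  = vapply(atoms, `[[`, "", "element"),
    charge   = vapply(atoms, `[[`, 0L, "charge"),
    isotope  = vapply(atoms, `[[`, 0L, "isotope"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    nH       = vapply(atoms, function(x) as.integer(x$nH), 0L),
    stringsAsFactors = FALSE
  )
  explicit_h <- vapply(atoms, `[[`, FALSE, "explicit_h")
  nb <- length(abonds)
  b <- data.frame(
    a1 = vapply(abonds, `[[`, 0L, "a1"),
    a2 = vapply(abonds, `[[`, 0L, "a2"),
    order = integer(nb), aromatic = logical(nb), ring = logical(nb)
  )
  sym <- vapply(abonds, function(x) if (is.na(x$sym)) "" else x$sym, "")
  for (k in seq_len(nb)) {
    both_arom <- a$aromatic[b$a1[k]] && a$aromatic[b$a2[k]]
    b$order[k] <- switch(sym[k], "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L, 1L)
    b$aromatic[k] <- (sym[k] == ":") || (sym[k] == "" && both_arom)
  }
  mol <- new_mol(a, b, name = name, source_id = source_id)
  mol <- with_rings(mol)
  # aromatic default bonds outside rings are single (e.g. biphenyl)
  fix <- mol$bonds$aromatic & !mol$bonds$ring
  mol$bonds$aromatic[fix] <- FALSE
  # implicit hydrogens for organic-subset atoms
  mol$atoms$nH <- compute_implicit_h(mol, explicit_h)
  if (kekulize && any(mol$bonds$aromatic)) mol <- kekulize_mol(mol)
  mol
}

compute_implicit_h <- function(mol, explicit_h) {
  nH <- mol$atoms$nH
  bosum <- numeric(n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    o <- if (b$aromatic[k]) 1.5 else b$order[k]
    bosum[b$a1[k]] <- bosum[b$a1[k]] + o
    bosum[b$a2[k]] <- bosum[b$a2[k]] + o
  }
  for (i in seq_len(n_atoms(mol))) {
    if (explicit_h[i]) next  # bracket atoms state their H count
    el <- mol$atoms$element[i]
    val <- .ORGANIC_VALENCE[el]
    if (is.na(val)) { nH[i] <- 0L; next }
    nH[i] <- max(0L, as.integer(val) - as.integer(ceiling(bosum[i])))
  }
  nH
}

# Kekulization: assign single/double orders to aromatic bonds so every
# aromatic atom that needs one double bond gets exactly one (perfect
# matching by backtracking over the aromatic subgraph).
kekulize_mol <- function(mol) {
  arom_bonds <- which(mol$bonds$aromatic)
  if (!length(arom_bonds)) return(mol)
  arom_atoms <- sort(unique(c(mol$bonds$a1[arom_bonds], mol$bonds$a2[arom_bonds])))
  needs <- logical(n_atoms(mol))
  b <- mol$bonds
  for (i in arom_atoms) {
    el <- mol$atoms$element[i]; chg <- mol$atoms$charge[i]
    # bond-order sum counting aromatic bonds as single + implicit H
    bos <- mol$atoms$nH[i]
    has_exo_double <- FALSE
    for (k in seq_len(nrow(b))) {
      if (b$a1[k] != i && b$a2[k] != i) next
      bos <- bos + (if (b$aromatic[k]) 1L else b$order[k])
      if (!b$aromatic[k] && b$order[k] >= 2L) has_exo_double <- TRUE
    }
    target <- switch(el,
      C = 4L + chg, N = 3L + chg, P = 3L + chg, O = 2L + chg,
      S = 2L + chg, B = 3L - chg, 0L)
    needs[i] <- !has_exo_double && (target - bos) >= 1L
  }
  # backtracking matching over aromatic bonds
  assign <- integer(length(arom_bonds))  # 0 unset, 1 single, 2 double
  satisfied <- !needs
  bt <- function(k) {
    if (k > length(arom_bonds)) return(all(satisfied[arom_atoms]))
    kb <- arom_bonds[k]
    i <- b$a1[kb]; j <- b$a2[kb]
    if (!satisfied[i] && !satisfied[j]) {
      satisfied[i] <<- TRUE; satisfied[j] <<- TRUE; assign[k] <<- 2L
      if (bt(k + 1L)) return(TRUE)
      satisfied[i] <<- FALSE; satisfied[j] <<- FALSE
    }
    assign[k] <<- 1L
    if (bt(k + 1L)) return(TRUE)
    assign[k] <<- 0L
    FALSE
  }
  if (!bt(1L)) {
    stop("no consistent Kekéle assignment for aromatic system involving atoms ",
         paste(arom_atoms, collapse = ","), " in ",
         if (nzchar(mol$name)) mol$name else "molecule")
  }
  mol$bonds$order[arom_bonds] <- assign
  mol
}
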