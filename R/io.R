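# Readers and writers for building-block collections: SMILES lists
# (one molecule per line, optional tab-separated id) and SDF V2000.

#' Read building blocks from a SMILES or SDF file
#'
#' Format is chosen by extension (`.smi`/`.smiles`/`.txt` vs `.sdf`).
#' Molecules that fail to parse are returned as rejections with reason
#' `parse_error` rather than raising.
#'
#' @param path input file.
#' @return List of `ss_mol` and/or `ss_rejection` objects.
#' @export
read_building_blocks <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) read_sdf(path)
  else read_smiles_file(path)
}

#' @rdname read_building_blocks
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (t in seq_along(lines)) {
    parts <- strsplit(trimws(lines[t]), "[\t ]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) > 1L) parts[2] else sprintf("mol_%04d", t)
    out[[t]] <- tryCatch(
      parse_smiles(smi, name = id, source_id = id),
      error = function(e) structure(list(source_id = id, name = id,
                                         reason = "parse_error"),
                                    class = "ss_rejection"))
  }
  out
}

#' @rdname read_building_blocks
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split records on $$$$
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (!length(rec) || all(!nzchar(trimws(rec)))) next
    id <- trimws(rec[1])
    mol <- tryCatch(parse_sdf_record(rec, id),
      error = function(e) structure(list(source_id = id, name = id,
                                         reason = "parse_error"),
                                    class = "ss_rejection"))
    out[[length(out) + 1L]] <- mol
  }
  out
}

parse_sdf_record <- function(rec, id) {
  counts <- rec[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("bad counts line")
  atoms <- data.frame(element = character(na), charge = integer(na),
                      isotope = integer(na), aromatic = logical(na),
                      nH = integer(na))
  for (i in seq_len(na)) {
    ln <- rec[4 + i]
    atoms$element[i] <- trimws(substr(ln, 32, 34))
    chg <- as.integer(substr(ln, 37, 39))
    atoms$charge[i] <- if (is.na(chg) || chg == 0L) 0L
                       else 4L - chg  # ctab charge code: 1=+3 ... 7=-3
  }
  bonds <- empty_bonds()
  explicit_h_bonds <- integer()
  for (k in seq_len(nb)) {
    ln <- rec[4 + na + k]
    a1 <- as.integer(substr(ln, 1, 3)); a2 <- as.integer(substr(ln, 4, 6))
    o <- as.integer(substr(ln, 7, 9))
    arom <- !is.na(o) && o == 4L
    bonds <- rbind(bonds, data.frame(a1 = a1, a2 = a2,
                                     order = if (arom) 1L else o,
                                     aromatic = arom, ring = FALSE))
  }
  # M CHG overrides
  for (ln in rec[grepl("^M  CHG", rec)]) {
    fields <- as.integer(strsplit(trimws(substring(ln, 7)), "[ ]+")[[1]])
    ncg <- fields[1]
    for (t in seq_len(ncg)) {
      atoms$charge[fields[2 * t]] <- fields[2 * t + 1]
    }
  }
  mol <- new_mol(atoms, bonds, name = id, source_id = id)
  # fold explicit hydrogens into neighbour nH
  hs <- which(mol$atoms$element == "H")
  if (length(hs)) {
    adj <- mol_adj(mol)
    for (h in hs) {
      nb1 <- adj[[h]]$nbr
      if (length(nb1)) mol$atoms$nH[nb1[1]] <- mol$atoms$nH[nb1[1]] + 1L
    }
    mol <- mol_delete_atoms(mol, hs)
  }
  mol <- with_rings(mol)
  # implicit hydrogens for standard-valence atoms (SDF gives none)
  bosum <- atom_total_order(mol) - mol$atoms$nH
  for (i in seq_len(n_atoms(mol))) {
    el <- mol$atoms$element[i]
    val <- .ORGANIC_VALENCE[el]
    if (is.na(val) || mol$atoms$charge[i] != 0L) next
    mol$atoms$nH[i] <- mol$atoms$nH[i] +
      max(0L, as.integer(val) - as.integer(bosum[i]))
  }
  if (any(mol$bonds$aromatic)) mol <- kekulize_mol(mol)
  mol
}

#' Write molecules as a SMILES file
#'
#' Canonical SMILES, one per line, tab-separated id.
#'
#' @param mols list of `ss_mol`.
#' @param path output path.
#' @export
write_smiles_file <- function(mols, path) {
  lines <- vapply(mols, function(m) {
    paste(write_smiles(m),
          if (nzchar(m$source_id)) m$source_id else m$name, sep = "\t")
  }, "")
  writeLines(lines, path)
}

#' Standardize a building-block collection
#'
#' Runs [standardize()] over a list of parsed molecules (or rejections
#' from the reader) and assembles the conservation report.
#'
#' @param mols list from [read_building_blocks()].
#' @param mw_cap,metal_set passed to [standardize()].
#' @return List with `mols` (standardized survivors) and `report` (class
#'   `ss_std_report`: `input_count`, `retained_count`, `rejections`).
#' @export
standardize_collection <- function(mols, mw_cap = 700,
                                   metal_set = .DEFAULT_METAL_SET) {
  kept <- list()
  rej <- data.frame(source_id = character(), reason = character())
  for (m in mols) {
    r <- if (is_rejection(m)) m else standardize(m, mw_cap, metal_set)
    if (is_rejection(r)) {
      rej <- rbind(rej, data.frame(source_id = r$source_id, reason = r$reason))
    } else {
      kept[[length(kept) + 1L]] <- r
    }
  }
  report <- structure(list(input_count = length(mols),
                           retained_count = length(kept),
                           rejections = rej),
                      class = "ss_std_report")
  stopifnot(report$input_count == report$retained_count + nrow(rej))
  list(mols = kept, report = report)
}

#' @export
print.ss_std_report <- function(x, ...) {
  cat(sprintf("standardization: %d in, %d retained, %d rejected\n",
              x$input_count, x$retained_count, nrow(x$rejections)))
  if (nrow(x$rejections)) {
    tab <- table(x$rejections$reason)
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}
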