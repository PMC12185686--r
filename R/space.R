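# The combinatorial fragment space: synthon construction, topology
# graphs (two nodes, one edge per sub-reaction), exact counting without
# enumeration, seeded sampled enumeration, retro-validation, membership
# by retro-decomposition, additive-property histograms by convolution,
# and a plain-text serialization.

.COUNT_LIMIT <- 2^53  # doubles are exact integers below this

# product-pattern edges that join the two reactant sides (formed bonds)
link_slots <- function(rule) {
  pg <- rule$product_graph
  side_of_map <- rule$side_of_map
  slots <- list()
  for (e in pg$edges) {
    ma <- e$start + 1L; mb <- e$end + 1L
    sa <- side_of_map[[as.character(ma)]]
    sb <- side_of_map[[as.character(mb)]]
    if (is.null(sa) || is.null(sb) || sa == sb) next
    m1 <- if (sa == 1L) ma else mb
    m2 <- if (sa == 1L) mb else ma
    slots[[length(slots) + 1L]] <- list(map1 = m1, map2 = m2,
                                        order = bond_text_order(e$bond_text))
  }
  if (!length(slots)) stop("rule ", rule$transform_id,
                           " forms no bond between its reactant sides")
  ord <- order(vapply(slots, `[[`, 0L, "map1"))
  slots <- slots[ord]
  for (t in seq_along(slots)) slots[[t]]$slot <- t
  slots
}

# hydrogen-count pins on product nodes: map number -> exact H
product_h_pins <- function(rule) {
  pins <- integer()
  for (nd in rule$product_graph$nodes) {
    for (p in nd$properties) {
      if (p$keyword == "HS" && p$op == "=" && !p$negated)
        pins[as.character(nd$index + 1L)] <- as.integer(p$args[1])
    }
  }
  pins
}

# same-side product bond-order targets: list of (map_a, map_b, order)
same_side_edges <- function(rule, side) {
  pg <- rule$product_graph
  side_of_map <- rule$side_of_map
  out <- list()
  for (e in pg$edges) {
    ma <- e$start + 1L; mb <- e$end + 1L
    sa <- side_of_map[[as.character(ma)]]
    sb <- side_of_map[[as.character(mb)]]
    if (is.null(sa) || is.null(sb) || sa != sb || sa != side) next
    # only explicit bond orders rewrite the reactant; aromatic (:) and
    # any (~) product bonds assert matching, not a Kekulé edit
    if (!(e$bond_text %in% c("-", "=", "#"))) next
    out[[length(out) + 1L]] <- list(map_a = ma, map_b = mb,
                                    order = bond_text_order(e$bond_text))
  }
  out
}

#' Build synthons for one sub-reaction
#'
#' Converts each surviving reactant into a synthon: the leaving group is
#' deleted, same-side bond orders are set to their product values, typed
#' link atoms (dummies carrying the link slot in the isotope field) are
#' attached with the formed bond's order, and hydrogen counts are
#' adjusted by bond-order conservation (or pinned by the product
#' pattern). Reactants whose implied product environment violates the
#' valence model are dropped with a reason.
#'
#' @param subreaction an `ss_subreaction`.
#' @param model aromaticity model used for canonical synthon keys.
#' @param valence_table allowed-valence table.
#' @return List with `side1`, `side2` (lists of `ss_synthon`) and
#'   `dropped` (data frame).
#' @export
build_synthons <- function(subreaction, model = "DEFAULT",
                           valence_table = default_valence_table()) {
  rule <- subreaction$rule
  slots <- link_slots(rule)
  pins <- product_h_pins(rule)
  dropped <- data.frame(bb_id = character(), side = integer(),
                        reason = character())
  mk_side <- function(entries, side) {
    out <- list()
    for (x in entries) {
      syn <- tryCatch(
        synthon_from_record(x$record, rule, slots, pins, side, model,
                            valence_table),
        error = function(e) structure(list(msg = conditionMessage(e)),
                                      class = "ss_drop"))
      if (inherits(syn, "ss_drop")) {
        dropped <<- rbind(dropped, data.frame(bb_id = x$record$bb$source_id,
                                              side = side, reason = syn$msg))
      } else out[[length(out) + 1L]] <- syn
    }
    out
  }
  list(side1 = mk_side(subreaction$group_1, 1L),
       side2 = mk_side(subreaction$group_2, 2L),
       dropped = dropped)
}

synthon_from_record <- function(record, rule, slots, pins, side, model,
                                valence_table) {
  bb <- record$bb
  assign <- record$assignments[[1]]
  pat <- rule$reactant_patterns[[side]]
  maps <- vapply(pat$atoms, `[[`, 0L, "map")
  core <- maps > 0L & maps <= rule$n_core
  mapped_atoms <- assign[core]
  map_numbers <- maps[core]
  atom_of_map <- stats::setNames(mapped_atoms, map_numbers)
  # leaving set incl. dangling substituents
  leaving_seed <- assign[!core]
  leaving <- integer()
  if (length(leaving_seed)) {
    keep0 <- setdiff(seq_len(n_atoms(bb)), mapped_atoms)
    sub <- mol_subset(bb, keep0)
    comp <- mol_components(sub)
    seed_local <- match(leaving_seed, keep0)
    for (cid in unique(comp[seed_local]))
      leaving <- c(leaving, keep0[comp == cid])
    leaving <- sort(unique(leaving))
  }
  # hydrogen bookkeeping: bonds lost to the leaving group
  h_gain <- stats::setNames(numeric(length(map_numbers)),
                            as.character(map_numbers))
  for (k in seq_len(nrow(bb$bonds))) {
    a1 <- bb$bonds$a1[k]; a2 <- bb$bonds$a2[k]
    if ((a1 %in% leaving) != (a2 %in% leaving)) {
      kept <- if (a1 %in% leaving) a2 else a1
      m <- map_numbers[match(kept, mapped_atoms)]
      if (!is.na(m)) h_gain[as.character(m)] <-
          h_gain[as.character(m)] + bb$bonds$order[k]
    }
  }
  keep <- setdiff(seq_len(n_atoms(bb)), leaving)
  frag <- mol_subset(bb, keep)
  remap <- match(seq_len(n_atoms(bb)), keep)
  loc_of_map <- stats::setNames(remap[mapped_atoms],
                                as.character(map_numbers))
  # same-side bond-order edits
  for (e in same_side_edges(rule, side)) {
    i <- loc_of_map[[as.character(e$map_a)]]
    j <- loc_of_map[[as.character(e$map_b)]]
    k <- bond_between(frag, i, j)
    if (!length(k)) stop("product requires a bond between mapped atoms ",
                         e$map_a, " and ", e$map_b, " that the reactant lacks")
    delta <- e$order - frag$bonds$order[k]
    if (delta != 0) {
      frag$bonds$order[k] <- e$order
      frag$bonds$aromatic[k] <- FALSE
      for (m in c(e$map_a, e$map_b)) {
        h_gain[as.character(m)] <- h_gain[as.character(m)] - delta
      }
    }
  }
  # link atoms for formed bonds
  for (sl in slots) {
    m <- if (side == 1L) sl$map1 else sl$map2
    i <- loc_of_map[[as.character(m)]]
    frag$atoms <- rbind(frag$atoms,
      data.frame(element = "*", charge = 0L, isotope = sl$slot,
                 aromatic = FALSE, nH = 0L))
    frag$bonds <- rbind(frag$bonds,
      data.frame(a1 = i, a2 = nrow(frag$atoms), order = sl$order,
                 aromatic = FALSE, ring = FALSE))
    h_gain[as.character(m)] <- h_gain[as.character(m)] - sl$order
  }
  # apply hydrogen adjustments / product pins
  for (m in names(loc_of_map)) {
    i <- loc_of_map[[m]]
    if (m %in% names(pins)) {
      frag$atoms$nH[i] <- pins[[m]]
    } else {
      newH <- frag$atoms$nH[i] + h_gain[[m]]
      if (newH < 0) stop("valence: mapped atom ", m,
                         " has no hydrogen left to form the product bond")
      frag$atoms$nH[i] <- as.integer(newH)
    }
  }
  frag <- with_rings(frag)
  if (!check_valence(frag, valence_table))
    stop("valence: non-favored valence state in product environment")
  frag <- perceive_aromaticity(frag, model)
  structure(list(fragment = frag,
                 key = write_smiles(frag),
                 provenance = list(bb_id = bb$source_id,
                                   transform_id = rule$transform_id,
                                   side = side,
                                   variant_tag = rule$variant_tag),
                 mass_contribution = mol_mw(frag)),
            class = "ss_synthon")
}

#' @export
print.ss_synthon <- function(x, ...) {
  cat(sprintf("<synthon %s (side %d of %d): %s>\n", x$provenance$bb_id,
              x$provenance$side, x$provenance$transform_id, x$key))
  invisible(x)
}

#' Build a fragment space from sub-reactions
#'
#' One topology graph per sub-reaction: two synthon-set nodes joined by
#' the link-type edge. The manifest records policies and the aromaticity
#' model for provenance.
#'
#' @param subreactions list of `ss_subreaction` from
#'   [filter_building_blocks()].
#' @param name space name.
#' @param model aromaticity model (`"DEFAULT"` or `"CACTVS"`).
#' @param policy duplicate policy recorded in the manifest.
#' @return An object of class `ss_fragment_space`.
#' @export
build_space <- function(subreactions, name = "space", model = "DEFAULT",
                        policy = "SPACE") {
  graphs <- list()
  dropped <- data.frame(bb_id = character(), side = integer(),
                        reason = character())
  for (sr in subreactions) {
    syn <- build_synthons(sr, model = model)
    dropped <- rbind(dropped, syn$dropped)
    rule <- sr$rule
    graphs[[length(graphs) + 1L]] <- list(
      transform_id = rule$transform_id,
      variant_tag = rule$variant_tag,
      name = rule$name,
      reactant_smarts = rule$reactant_smarts,
      product_smarts = rule$product_smarts,
      side_of_map = rule$side_of_map,
      slots = link_slots(rule),
      pairing_reason = sr$pairing_reason,
      side1 = syn$side1, side2 = syn$side2,
      product_pattern = rule$product_pattern)
  }
  structure(list(name = name,
                 graphs = graphs,
                 manifest = list(name = name, aromaticity_model = model,
                                 policy = policy,
                                 created = "synthonspace",
                                 n_subreactions = length(graphs)),
                 dropped = dropped),
            class = "ss_fragment_space")
}

#' @export
print.ss_fragment_space <- function(x, ...) {
  cat(sprintf("<fragment space '%s': %d sub-reaction(s), %s products (model %s)>\n",
              x$name, length(x$graphs),
              format(count_products(x), big.mark = ","),
              x$manifest$aromaticity_model))
  invisible(x)
}

#' Exact product count
#'
#' Sum over topology graphs of |side1| x |side2|, computed exactly (an
#' error is raised beyond 2^53 where double arithmetic would round;
#' published spaces reach 1e10, far below that).
#'
#' @param space an `ss_fragment_space`.
#' @return Exact count as a double holding an integer value.
#' @export
count_products <- function(space) {
  total <- 0
  for (g in space$graphs) {
    n <- length(g$side1) * length(g$side2)
    total <- total + n
    if (total >= .COUNT_LIMIT)
      stop("product count exceeds exact double-integer range (2^53)")
  }
  total
}

# join two synthon fragments at their typed link atoms
assemble_product <- function(syn1, syn2, model = "DEFAULT") {
  f1 <- syn1$fragment; f2 <- syn2$fragment
  n1 <- n_atoms(f1)
  atoms <- rbind(f1$atoms, f2$atoms)
  b2 <- f2$bonds; b2$a1 <- b2$a1 + n1; b2$a2 <- b2$a2 + n1
  bonds <- rbind(f1$bonds, b2)
  mol <- new_mol(atoms, bonds)
  dummies <- which(mol$atoms$element == "*" & mol$atoms$isotope > 0L)
  adj <- mol_adj(mol)
  drop <- integer()
  for (slot in sort(unique(mol$atoms$isotope[dummies]))) {
    ds <- dummies[mol$atoms$isotope[dummies] == slot]
    if (length(ds) != 2L)
      stop("link slot ", slot, " does not pair up at assembly")
    anchors <- vapply(ds, function(d) adj[[d]]$nbr[1], 0L)
    orders <- vapply(ds, function(d) mol$bonds$order[adj[[d]]$bond[1]], 0L)
    if (orders[1] != orders[2])
      stop("link slot ", slot, " has inconsistent bond orders")
    mol$bonds <- rbind(mol$bonds,
      data.frame(a1 = anchors[1], a2 = anchors[2], order = orders[1],
                 aromatic = FALSE, ring = FALSE))
    drop <- c(drop, ds)
  }
  mol <- mol_delete_atoms(mol, drop)
  mol <- with_rings(mol)
  if (!check_valence(mol))
    stop("assembly produced an invalid valence state (synthon bug)")
  perceive_aromaticity(mol, model)
}

#' Enumerate products (full or sampled)
#'
#' Uniform, seeded sampling without replacement over the pair lattice of
#' each sub-reaction; no product list is ever materialized beyond the
#' requested sample. When `limit` covers the whole space the enumeration
#' is complete and deterministic.
#'
#' @param space an `ss_fragment_space`.
#' @param limit maximum number of products to return (per space).
#' @param seed integer seed; the same seed yields a byte-identical
#'   sample.
#' @return Data frame with `smiles`, `graph` (sub-reaction index),
#'   `transform_id`, `variant_tag`, `bb1`, `bb2`.
#' @export
enumerate_products <- function(space, limit = Inf, seed = 1L) {
  model <- space$manifest$aromaticity_model
  sizes <- vapply(space$graphs, function(g)
    length(g$side1) * length(g$side2), 0)
  total <- sum(sizes)
  take <- min(limit, total)
  idx <- if (take >= total) seq_len(total)
         else withr_seed(seed, sample.int(total, take))
  idx <- sort(idx)
  offs <- cumsum(c(0, sizes))
  out <- vector("list", length(idx))
  for (t in seq_along(idx)) {
    gidx <- findInterval(idx[t] - 1, offs, rightmost.closed = FALSE)
    g <- space$graphs[[gidx]]
    within <- idx[t] - offs[gidx] - 1  # 0-based
    n2 <- length(g$side2)
    i1 <- within %/% n2 + 1
    i2 <- within %% n2 + 1
    syn1 <- g$side1[[i1]]; syn2 <- g$side2[[i2]]
    mol <- assemble_product(syn1, syn2, model)
    out[[t]] <- data.frame(smiles = write_smiles(mol), graph = gidx,
                           transform_id = g$transform_id,
                           variant_tag = g$variant_tag,
                           bb1 = syn1$provenance$bb_id,
                           bb2 = syn2$provenance$bb_id)
  }
  if (!length(out)) {
    return(data.frame(smiles = character(), graph = integer(),
                      transform_id = integer(), variant_tag = character(),
                      bb1 = character(), bb2 = character()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# run expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# decompose a product molecule along one product-pattern embedding into
# the two canonical synthon keys; NULL when the cut does not split in two
cut_product <- function(mol, g, assign, model) {
  pat_maps <- vapply(g$product_pattern$atoms, `[[`, 0L, "map")
  atom_of_map <- stats::setNames(assign[pat_maps > 0L],
                                 pat_maps[pat_maps > 0L])
  cut_bonds <- list()
  for (sl in g$slots) {
    a <- atom_of_map[[as.character(sl$map1)]]
    b <- atom_of_map[[as.character(sl$map2)]]
    k <- bond_between(mol, a, b)
    if (!length(k)) return(NULL)
    cut_bonds[[length(cut_bonds) + 1L]] <- list(a = a, b = b, k = k[1],
                                                slot = sl$slot,
                                                order = mol$bonds$order[k[1]])
  }
  work <- mol
  kill <- vapply(cut_bonds, `[[`, 0L, "k")
  work$bonds <- work$bonds[-kill, , drop = FALSE]
  rownames(work$bonds) <- NULL
  # attach typed dummies at both cut ends
  for (cb in cut_bonds) {
    for (end in c(cb$a, cb$b)) {
      work$atoms <- rbind(work$atoms,
        data.frame(element = "*", charge = 0L, isotope = cb$slot,
                   aromatic = FALSE, nH = 0L))
      work$bonds <- rbind(work$bonds,
        data.frame(a1 = end, a2 = nrow(work$atoms), order = cb$order,
                   aromatic = FALSE, ring = FALSE))
    }
  }
  comp <- mol_components(work)
  if (length(unique(comp)) != 2L) return(NULL)
  side_of_comp <- integer(2)
  m1 <- atom_of_map[[as.character(g$slots[[1]]$map1)]]
  m2 <- atom_of_map[[as.character(g$slots[[1]]$map2)]]
  c1 <- comp[m1]; c2 <- comp[m2]
  if (c1 == c2) return(NULL)
  piece <- function(cid) {
    p <- mol_subset(work, which(comp == cid))
    p <- with_rings(p)
    p <- perceive_aromaticity(p, model)
    write_smiles(p)
  }
  list(key1 = piece(c1), key2 = piece(c2))
}

#' Retro-validate an assembled product
#'
#' Applies the transform backwards: the product must match the product
#' pattern, and cutting the formed bonds must regenerate exactly the
#' recorded synthons of the two reactants originally used.
#'
#' @param product an `ss_mol` (a product as assembled/perceived), or a
#'   SMILES string.
#' @param space the `ss_fragment_space`.
#' @param graph sub-reaction index within the space.
#' @param bb1,bb2 building-block ids recorded for the product.
#' @return `TRUE` or `FALSE`.
#' @export
retro_validate <- function(product, space, graph, bb1, bb2) {
  g <- space$graphs[[graph]]
  model <- space$manifest$aromaticity_model
  if (is.character(product)) {
    product <- perceive_aromaticity(parse_smiles(product), model)
  }
  key1 <- NULL; key2 <- NULL
  for (s in g$side1) if (s$provenance$bb_id == bb1) key1 <- s$key
  for (s in g$side2) if (s$provenance$bb_id == bb2) key2 <- s$key
  if (is.null(key1) || is.null(key2)) return(FALSE)
  assigns <- smarts_match(product, g$product_pattern)
  for (a in assigns) {
    cut <- cut_product(product, g, a, model)
    if (is.null(cut)) next
    if ((cut$key1 == key1 && cut$key2 == key2)) return(TRUE)
  }
  FALSE
}

#' Membership test by retro-decomposition
#'
#' Cuts the query at every embedding of every sub-reaction's product
#' pattern and looks the canonicalized pieces up in the synthon indexes;
#' exact (canonical-SMILES identity), with one provenance entry per
#' construction route.
#'
#' @param space an `ss_fragment_space`.
#' @param query a SMILES string or `ss_mol`.
#' @return List of provenance lists (`graph`, `transform_id`,
#'   `variant_tag`, `bb1`, `bb2`); empty when not constructible.
#' @export
space_contains <- function(space, query) {
  model <- space$manifest$aromaticity_model
  mol <- if (is.character(query)) {
    perceive_aromaticity(parse_smiles(query), model)
  } else query
  hits <- list()
  for (gi in seq_along(space$graphs)) {
    g <- space$graphs[[gi]]
    if (!length(g$side1) || !length(g$side2)) next
    index1 <- stats::setNames(seq_along(g$side1),
                              vapply(g$side1, `[[`, "", "key"))
    index2 <- stats::setNames(seq_along(g$side2),
                              vapply(g$side2, `[[`, "", "key"))
    assigns <- smarts_match(mol, g$product_pattern)
    seen <- character()
    for (a in assigns) {
      cut <- cut_product(mol, g, a, model)
      if (is.null(cut)) next
      i1 <- index1[cut$key1]; i2 <- index2[cut$key2]
      if (is.na(i1) || is.na(i2)) next
      dk <- paste(i1, i2)
      if (dk %in% seen) next
      seen <- c(seen, dk)
      hits[[length(hits) + 1L]] <- list(
        graph = gi, transform_id = g$transform_id,
        variant_tag = g$variant_tag,
        bb1 = g$side1[[i1]]$provenance$bb_id,
        bb2 = g$side2[[i2]]$provenance$bb_id)
    }
  }
  hits
}

# --- additive-property histograms -------------------------------------

synthon_descriptor <- function(syn, descriptor) {
  frag <- syn$fragment
  real <- frag$atoms$element != "*"
  switch(descriptor,
    MW = syn$mass_contribution,
    HBD = sum(real & frag$atoms$element %in% c("N", "O", "S") &
                frag$atoms$nH > 0L),
    HBA = sum(real & frag$atoms$element %in% c("N", "O")),
    ROTB = {
      b <- frag$bonds
      dummy <- which(!real)
      sum(b$order == 1L & !b$ring & !b$aromatic &
            !(b$a1 %in% dummy) & !(b$a2 %in% dummy))
    },
    stop("unsupported descriptor '", descriptor,
         "' (additive descriptors only: MW, HBD, HBA, ROTB)"))
}

graph_forms_ring <- function(g) length(g$slots) > 1L

#' Property histogram without enumeration
#'
#' Computes the exact distribution of an additive descriptor over all
#' products by discrete convolution of the per-side value multisets,
#' graph by graph. Supported descriptors: `MW` (g/mol), `HBD`, `HBA`,
#' and `ROTB` (acyclic heavy-atom single-bond count; a link correction
#' of one per formed acyclic single bond). `ROTB` is refused on
#' ring-forming sub-reactions, where bond cyclicality is not additive
#' over synthons.
#'
#' @param space an `ss_fragment_space`.
#' @param descriptor one of `"MW"`, `"HBD"`, `"HBA"`, `"ROTB"`.
#' @param breaks histogram bin edges covering the value range.
#' @return Object of class `ss_prop_histogram`: `descriptor`, `breaks`,
#'   `counts` (exact), plus the raw value/count table.
#' @export
property_histograms <- function(space, descriptor = "MW", breaks = NULL) {
  vals <- numeric(); cnts <- numeric()
  addv <- function(v, n) {
    i <- match(v, vals)
    new <- is.na(i)
    if (any(new)) {
      vals <<- c(vals, v[new]); cnts <<- c(cnts, numeric(sum(new)))
      i <- match(v, vals)
    }
    cnts[i] <<- cnts[i] + n
  }
  for (g in space$graphs) {
    if (!length(g$side1) || !length(g$side2)) next
    if (descriptor == "ROTB" && graph_forms_ring(g))
      stop("unsupported descriptor 'ROTB' on ring-forming sub-reaction ",
           g$transform_id, ": bond cyclicality is not additive over synthons")
    link_corr <- if (descriptor == "ROTB") {
      sum(vapply(g$slots, function(sl) as.integer(sl$order == 1L), 0L))
    } else 0
    v1 <- vapply(g$side1, synthon_descriptor, 0, descriptor = descriptor)
    v2 <- vapply(g$side2, synthon_descriptor, 0, descriptor = descriptor)
    t1 <- table(round(v1, 6)); t2 <- table(round(v2, 6))
    a1 <- as.numeric(names(t1)); a2 <- as.numeric(names(t2))
    for (i in seq_along(a1)) {
      addv(round(a1[i] + a2 + link_corr, 6),
           as.numeric(t1[i]) * as.numeric(t2))
    }
  }
  ord <- order(vals)
  vals <- vals[ord]; cnts <- cnts[ord]
  if (is.null(breaks)) {
    breaks <- if (descriptor == "MW")
      seq(floor(min(vals, 0)), ceiling(max(vals, 1)) + 50, by = 50)
    else seq(-0.5, max(vals, 0) + 0.5, by = 1)
  }
  bin <- findInterval(vals, breaks, rightmost.closed = TRUE)
  counts <- numeric(length(breaks) - 1L)
  for (i in seq_along(vals)) {
    if (bin[i] >= 1L && bin[i] <= length(counts))
      counts[bin[i]] <- counts[bin[i]] + cnts[i]
  }
  structure(list(descriptor = descriptor, breaks = breaks, counts = counts,
                 values = vals, value_counts = cnts),
            class = "ss_prop_histogram")
}

#' @export
print.ss_prop_histogram <- function(x, ...) {
  cat(sprintf("<%s histogram: %s products in %d bins>\n", x$descriptor,
              format(sum(x$counts), big.mark = ","), length(x$counts)))
  invisible(x)
}

#' @export
plot.ss_prop_histogram <- function(x, ...) {
  mids <- (head(x$breaks, -1) + x$breaks[-1]) / 2
  graphics::barplot(x$counts, names.arg = signif(mids, 3),
                    xlab = x$descriptor, ylab = "products", ...)
  invisible(x)
}

#' Coverage of one space in another
#'
#' For each sub-reaction of `space_a`, samples up to `per_transform_n`
#' products (seeded) and reports the fraction found in `space_b` by
#' exact membership, aggregated per transform.
#'
#' @param space_a,space_b fragment spaces.
#' @param per_transform_n sample cap per sub-reaction (default 1000).
#' @param seed integer seed.
#' @return Data frame with `transform_id`, `sampled`, `found`,
#'   `fraction`.
#' @export
coverage_estimate <- function(space_a, space_b, per_transform_n = 1000L,
                              seed = 1L) {
  res <- list()
  for (gi in seq_along(space_a$graphs)) {
    g <- space_a$graphs[[gi]]
    n <- length(g$side1) * length(g$side2)
    if (n == 0) next
    sub <- space_a
    sub$graphs <- space_a$graphs[gi]
    smp <- enumerate_products(sub, limit = per_transform_n,
                              seed = seed + gi)
    found <- vapply(smp$smiles, function(s)
      length(space_contains(space_b, s)) > 0L, TRUE)
    res[[length(res) + 1L]] <- data.frame(transform_id = g$transform_id,
                                          sampled = nrow(smp),
                                          found = sum(found))
  }
  agg <- do.call(rbind, res)
  out <- stats::aggregate(cbind(sampled, found) ~ transform_id, agg, sum)
  out$fraction <- out$found / out$sampled
  out
}

# --- serialization -----------------------------------------------------

#' Serialize / load a fragment space
#'
#' Writes a directory with `manifest.json` and per-sub-reaction synthon
#' SMILES files (link atoms as isotope-typed dummies). `load_space()`
#' reproduces counts, histograms and membership results exactly.
#'
#' @param space an `ss_fragment_space`.
#' @param dir target directory (created).
#' @return `serialize_space()`: `dir`, invisibly. `load_space()`: the
#'   reloaded `ss_fragment_space`.
#' @export
serialize_space <- function(space, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  graph_meta <- list()
  for (gi in seq_along(space$graphs)) {
    g <- space$graphs[[gi]]
    for (side in 1:2) {
      syns <- g[[paste0("side", side)]]
      fn <- sprintf("graph%03d_side%d.smi", gi, side)
      lines <- vapply(syns, function(s)
        paste(s$key, s$provenance$bb_id, sep = "\t"), "")
      writeLines(lines, file.path(dir, fn))
    }
    graph_meta[[gi]] <- list(
      transform_id = g$transform_id, variant_tag = g$variant_tag,
      name = g$name, reactant_smarts = as.list(g$reactant_smarts),
      product_smarts = g$product_smarts,
      side_of_map = as.list(g$side_of_map),
      slots = lapply(g$slots, function(s)
        list(map1 = s$map1, map2 = s$map2, order = s$order, slot = s$slot)),
      pairing_reason = g$pairing_reason,
      files = list(sprintf("graph%03d_side1.smi", gi),
                   sprintf("graph%03d_side2.smi", gi)),
      counts = list(length(g$side1), length(g$side2)))
  }
  manifest <- space$manifest
  manifest$graphs <- graph_meta
  manifest$product_count <- count_products(space)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname serialize_space
#' @param dir directory written by [serialize_space()].
#' @export
load_space <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  model <- manifest$aromaticity_model
  if (is.null(model)) stop("manifest lacks aromaticity_model")
  graphs <- list()
  for (gm in manifest$graphs) {
    read_side <- function(fn, side) {
      path <- file.path(dir, fn)
      if (!file.exists(path)) stop("missing synthon file ", fn)
      lines <- readLines(path, warn = FALSE)
      lapply(lines[nzchar(lines)], function(ln) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        frag <- perceive_aromaticity(parse_smiles(parts[1]), model)
        structure(list(fragment = frag, key = write_smiles(frag),
                       provenance = list(bb_id = parts[2],
                                         transform_id = gm$transform_id,
                                         side = side,
                                         variant_tag = gm$variant_tag),
                       mass_contribution = mol_mw(frag)),
                  class = "ss_synthon")
      })
    }
    side1 <- read_side(gm$files[[1]], 1L)
    side2 <- read_side(gm$files[[2]], 2L)
    if (length(side1) != gm$counts[[1]] || length(side2) != gm$counts[[2]])
      stop("synthon file lengths disagree with manifest counts")
    graphs[[length(graphs) + 1L]] <- list(
      transform_id = gm$transform_id, variant_tag = gm$variant_tag,
      name = gm$name,
      reactant_smarts = unlist(gm$reactant_smarts),
      product_smarts = gm$product_smarts,
      side_of_map = unlist(gm$side_of_map),
      slots = lapply(gm$slots, function(s)
        list(map1 = s$map1, map2 = s$map2, order = s$order, slot = s$slot)),
      pairing_reason = gm$pairing_reason,
      side1 = side1, side2 = side2,
      product_pattern = parse_smarts(gm$product_smarts))
  }
  structure(list(name = manifest$name, graphs = graphs,
                 manifest = manifest[setdiff(names(manifest),
                                             c("graphs", "product_count"))],
                 dropped = NULL),
            class = "ss_fragment_space")
}
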