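# Building-block selection per reactant pattern, duplicate policies,
# masked-variant preparation, and splitting of reactions into
# sub-reactions by KILL-path signature.

#' @export
print.ss_match_record <- function(x, ...) {
  cat(sprintf("<match: %s on side %d, %d embedding(s)>\n",
              x$bb$source_id, x$pattern_side, length(x$match_maps)))
  invisible(x)
}

# reaction-center maps of one side: mapped atoms with a formed (cross-side)
# bond, a changed same-side bond environment, or a deleted neighbour
reaction_center_maps <- function(rule, side) {
  g <- rule$reactant_graphs[[side]]
  n_core <- rule$n_core
  side_of_map <- rule$side_of_map
  pg <- rule$product_graph
  centers <- integer()
  node_map <- vapply(g$nodes, function(n)
    if (is.null(n$map_number)) NA_integer_ else n$map_number, 0L)
  leaving_nodes <- which(is.na(node_map) | node_map > n_core) - 1L
  # same-side bond sums in reactant pattern vs product pattern
  for (nd in g$nodes) {
    m <- nd$map_number
    if (is.na(m) || m > n_core) next
    formed <- FALSE; changed <- FALSE
    for (e in pg$edges) {
      ma <- e$start + 1L; mb <- e$end + 1L  # product node = map number
      if (m != ma && m != mb) next
      other <- if (m == ma) mb else ma
      s_other <- side_of_map[[as.character(other)]]
      if (!is.null(s_other) && s_other != side) formed <- TRUE
    }
    # bonds to leaving atoms in the reactant pattern
    for (e in g$edges) {
      if (e$start == nd$index || e$end == nd$index) {
        other <- if (e$start == nd$index) e$end else e$start
        if (other %in% leaving_nodes) changed <- TRUE
      }
    }
    if (formed || changed) centers <- c(centers, m)
  }
  sort(unique(centers))
}

unify_matches <- function(assigns, rule, side, policy) {
  if (length(assigns) <= 1L) return(assigns)
  if (policy == "LIB2020") {
    keys <- vapply(assigns, function(a) paste(sort(a), collapse = ","), "")
  } else {
    centers <- reaction_center_maps(rule, side)
    g <- rule$reactant_graphs[[side]]
    node_map <- vapply(g$nodes, function(n)
      if (is.null(n$map_number)) NA_integer_ else n$map_number, 0L)
    center_nodes <- which(node_map %in% centers)
    keys <- vapply(assigns, function(a)
      paste(a[center_nodes], collapse = ","), "")
  }
  assigns[!duplicated(keys)]
}

#' Select building blocks for the reactant patterns of a rule
#'
#' Applies the single-match rule under one of two duplicate policies.
#' `LIB2020` unifies embeddings covering the same atom set before
#' counting; `SPACE` unifies embeddings whose assignments agree on the
#' reaction-center atoms (so symmetric double matches yielding the same
#' product count once, while matches yielding different products —
#' product mixtures — exclude the block). Blocks matching both reactant
#' patterns are excluded, unless a KILL ruleset is supplied and all of
#' one side's matches are killed — then the surviving side is kept.
#'
#' @param rule an `ss_reaction_rule` with one or two reactant patterns.
#' @param bbs list of standardized, aromaticity-perceived `ss_mol`.
#' @param policy `"LIB2020"` or `"SPACE"`.
#' @param ruleset optional `ss_kill_ruleset` enabling the kill-rescue
#'   exception for both-side matchers.
#' @param check_valences reject blocks in non-favored valence states.
#' @return List with `records` (per-block `ss_match_record`) and
#'   `excluded` (data frame of `bb_id`, `reason`).
#' @export
match_building_blocks <- function(rule, bbs, policy = c("SPACE", "LIB2020"),
                                  ruleset = NULL, check_valences = TRUE) {
  policy <- match.arg(policy)
  n_sides <- length(rule$reactant_patterns)
  if (n_sides > 2L) stop("rules with more than two reactant sides are unsupported")
  records <- list()
  excluded <- data.frame(bb_id = character(), reason = character())
  drop <- function(id, reason) {
    excluded <<- rbind(excluded, data.frame(bb_id = id, reason = reason))
  }
  for (bb in bbs) {
    id <- bb$source_id
    if (check_valences && !check_valence(bb)) { drop(id, "valence"); next }
    per_side <- vector("list", n_sides)
    for (s in seq_len(n_sides)) {
      assigns <- smarts_match(bb, rule$reactant_patterns[[s]])
      per_side[[s]] <- unify_matches(assigns, rule, s, policy)
    }
    counts <- lengths(per_side)
    if (all(counts == 0L)) { drop(id, "no_match"); next }
    if (any(counts > 1L)) { drop(id, "multi_match"); next }
    sides_hit <- which(counts == 1L)
    if (length(sides_hit) == 2L) {
      # both-side matcher: kill-rescue exception when a ruleset is given
      surviving <- sides_hit
      if (!is.null(ruleset)) {
        alive <- logical(2)
        for (s in sides_hit) {
          rec <- new_match_record(bb, s, per_side[[s]], rule)
          mv <- prepare_masked_variants(rec, rule)
          sig <- evaluate_kills(mv, ruleset, s, rule)
          alive[s] <- !sig$killed
        }
        surviving <- sides_hit[alive[sides_hit]]
      }
      if (length(surviving) != 1L) { drop(id, "both_sides"); next }
      sides_hit <- surviving
    }
    s <- sides_hit
    records[[length(records) + 1L]] <-
      new_match_record(bb, s, per_side[[s]], rule)
  }
  list(records = records, excluded = excluded)
}

new_match_record <- function(bb, side, assigns, rule) {
  pat <- rule$reactant_patterns[[side]]
  maps <- vapply(pat$atoms, `[[`, 0L, "map")
  match_maps <- lapply(assigns, function(a) {
    v <- a[maps > 0L]
    names(v) <- maps[maps > 0L]
    v
  })
  structure(list(bb = bb, pattern_side = side, match_maps = match_maps,
                 assignments = assigns),
            class = "ss_match_record")
}

#' Prepare the two masked variants of a matched reactant
#'
#' Variant (a) replaces the leaving group (reactant atoms absent from the
#' product pattern, together with their dangling substituents) by dummy
#' mask atoms and writes each backbone atom's map number into its isotope
#' slot (offset +100). Variant (b) additionally cuts every bond between
#' mapped atoms, so OFFPATH patterns cannot run along the reaction
#' substructure.
#'
#' @param record an `ss_match_record` with exactly one surviving match.
#' @param rule the matched `ss_reaction_rule`.
#' @return An object of class `ss_masked_variants` with `variant_a`,
#'   `variant_b`, and bookkeeping fields (`labels`, `leaving_atoms`).
#' @export
prepare_masked_variants <- function(record, rule) {
  if (length(record$assignments) != 1L)
    stop("masking requires exactly one surviving match")
  side <- record$pattern_side
  bb <- record$bb
  assign <- record$assignments[[1]]
  pat <- rule$reactant_patterns[[side]]
  maps <- vapply(pat$atoms, `[[`, 0L, "map")
  core <- maps > 0L & maps <= rule$n_core
  mapped_atoms <- assign[core]
  map_numbers <- maps[core]
  leaving_seed <- assign[!core]
  # extend the leaving set to dangling substituents: components of the
  # graph minus mapped atoms that contain a leaving-seed atom
  leaving <- integer()
  if (length(leaving_seed)) {
    keep <- setdiff(seq_len(n_atoms(bb)), mapped_atoms)
    sub <- mol_subset(bb, keep)
    comp <- mol_components(sub)
    back <- keep  # sub index -> original index
    seed_local <- match(leaving_seed, back)
    for (cid in unique(comp[seed_local])) leaving <- c(leaving, back[comp == cid])
    leaving <- sort(unique(leaving))
  }
  # variant a: delete leaving atoms, add a dummy per severed backbone bond
  va <- bb
  mask_bonds <- list()
  for (k in seq_len(nrow(bb$bonds))) {
    a1 <- bb$bonds$a1[k]; a2 <- bb$bonds$a2[k]
    if ((a1 %in% leaving) != (a2 %in% leaving)) {
      keep_atom <- if (a1 %in% leaving) a2 else a1
      mask_bonds <- c(mask_bonds, list(keep_atom))
    }
  }
  keep <- setdiff(seq_len(n_atoms(bb)), leaving)
  va <- mol_subset(bb, keep)
  remap <- match(seq_len(n_atoms(bb)), keep)  # old -> new index
  for (anchor in mask_bonds) {
    va$atoms <- rbind(va$atoms, data.frame(element = "*", charge = 0L,
                                           isotope = 0L, aromatic = FALSE,
                                           nH = 0L))
    va$bonds <- rbind(va$bonds, data.frame(a1 = remap[anchor],
                                           a2 = nrow(va$atoms),
                                           order = 1L, aromatic = FALSE,
                                           ring = FALSE))
  }
  labels <- integer(0)
  for (t in seq_along(mapped_atoms)) {
    new_idx <- remap[mapped_atoms[t]]
    va$atoms$isotope[new_idx] <- .KILL_ISO_OFFSET + map_numbers[t]
    labels[as.character(map_numbers[t])] <- new_idx
  }
  va <- with_rings(va)
  # variant b: cut all bonds among labelled atoms
  vb <- va
  lab_atoms <- unname(labels)
  cut <- with(vb$bonds, a1 %in% lab_atoms & a2 %in% lab_atoms)
  vb$bonds <- vb$bonds[!cut, , drop = FALSE]
  rownames(vb$bonds) <- NULL
  vb <- with_rings(vb)
  structure(list(variant_a = va, variant_b = vb, labels = labels,
                 leaving_atoms = leaving, record = record),
            class = "ss_masked_variants")
}

#' @export
print.ss_masked_variants <- function(x, ...) {
  cat(sprintf("<masked variants of %s: a=%s b=%s>\n", x$record$bb$source_id,
              write_smiles(x$variant_a), write_smiles(x$variant_b)))
  invisible(x)
}

#' @export
print.ss_subreaction <- function(x, ...) {
  cat(sprintf("<sub-reaction %d%s: %d x %d reactants (%s)>\n",
              x$rule$transform_id,
              if (nzchar(x$rule$variant_tag)) paste0("/", x$rule$variant_tag) else "",
              length(x$group_1), length(x$group_2), x$pairing_reason))
  invisible(x)
}

#' Split a rule into KILL-consistent sub-reactions
#'
#' Reactants with equal KILL-path signatures are grouped; groups are
#' paired when every cross-reactant statement is satisfied for all pairs
#' of the group product. Side-1 groups with identical compatible partner
#' sets are merged, so the union of sub-reaction product sets equals the
#' KILL-consistent pair set with no pair in two sub-reactions.
#'
#' @param rule an `ss_reaction_rule`.
#' @param side1,side2 lists of `list(record=, variants=, signature=)` for
#'   the surviving reactants of each side (see [evaluate_kills()]).
#' @param ruleset the `ss_kill_ruleset`.
#' @return List of `ss_subreaction` objects.
#' @export
split_subreactions <- function(rule, side1, side2, ruleset) {
  alive1 <- Filter(function(x) !x$signature$killed, side1)
  alive2 <- Filter(function(x) !x$signature$killed, side2)
  if (!length(alive1) || !length(alive2)) return(list())
  key1 <- vapply(alive1, function(x) signature_key(x$signature), "")
  key2 <- vapply(alive2, function(x) signature_key(x$signature), "")
  groups1 <- split(seq_along(alive1), key1)
  groups2 <- split(seq_along(alive2), key2)
  # compatibility between group representatives
  compat <- matrix(FALSE, length(groups1), length(groups2))
  for (i in seq_along(groups1)) {
    sig1 <- alive1[[groups1[[i]][1]]]$signature
    for (j in seq_along(groups2)) {
      sig2 <- alive2[[groups2[[j]][1]]]$signature
      compat[i, j] <- !pair_killed(sig1, sig2, ruleset, rule)
    }
  }
  # merge side-1 groups with equal compatible sets
  setkey <- apply(compat, 1, function(r) paste(as.integer(r), collapse = ""))
  out <- list()
  for (sk in unique(setkey)) {
    gi <- which(setkey == sk)
    gj <- which(compat[gi[1], ])
    if (!length(gj)) next
    idx1 <- unlist(groups1[gi], use.names = FALSE)
    idx2 <- unlist(groups2[gj], use.names = FALSE)
    out[[length(out) + 1L]] <- structure(list(
      rule = rule,
      group_1 = alive1[idx1],
      group_2 = alive2[idx2],
      pairing_reason = paste0("sig1={", paste(names(groups1)[gi], collapse = "|"),
                              "} sig2={", paste(names(groups2)[gj], collapse = "|"),
                              "}")), class = "ss_subreaction")
  }
  out
}

#' Run the full reactant-filtering pipeline for a set of rules
#'
#' For each rule (transform variant): match building blocks under the
#' policy, prepare masked variants, evaluate KILL statements and split
#' into sub-reactions. A block matched by two fusion variants of the same
#' transform is assigned to the lowest-numbered variant only, so variants
#' never produce duplicate products.
#'
#' @param rules list of `ss_reaction_rule` (e.g. one transform's variants,
#'   or a whole corpus).
#' @param bbs standardized, perceived building blocks.
#' @param policy duplicate policy, `"SPACE"` or `"LIB2020"`.
#' @param rulesets named list of `ss_kill_ruleset` keyed by transform id
#'   (as character); missing entries mean no KILL filtering.
#' @param deprotect remove protecting groups from matched reactants prior
#'   to masking/kill evaluation (fragments are stored deprotected).
#' @return List of `ss_subreaction` across all rules, with an
#'   `exclusions` attribute (data frame of bb_id, transform_id, reason).
#' @export
filter_building_blocks <- function(rules, bbs, policy = c("SPACE", "LIB2020"),
                                   rulesets = list(), deprotect = TRUE) {
  policy <- match.arg(policy)
  subreactions <- list()
  exclusions <- data.frame(bb_id = character(), transform_id = integer(),
                           variant_tag = character(), reason = character())
  assigned <- new.env(parent = emptyenv())  # "<tid>|<side>|<bb>" -> variant
  for (rule in rules) {
    ruleset <- rulesets[[as.character(rule$transform_id)]]
    if (is.null(ruleset))
      ruleset <- load_kill_ruleset(list(transform = rule$transform_id,
                                        statements = list(),
                                        untranslatable = list()))
    mres <- match_building_blocks(rule, bbs, policy, ruleset = ruleset)
    if (nrow(mres$excluded)) {
      exclusions <- rbind(exclusions,
        data.frame(bb_id = mres$excluded$bb_id,
                   transform_id = rule$transform_id,
                   variant_tag = rule$variant_tag,
                   reason = mres$excluded$reason))
    }
    sides <- list(list(), list())
    for (rec in mres$records) {
      k <- paste(rule$transform_id, rec$pattern_side, rec$bb$source_id,
                 sep = "|")
      if (!is.null(assigned[[k]])) next  # lower-numbered variant owns it
      if (deprotect) {
        dp <- remove_protecting_groups(rec$bb)
        if (length(dp$removed)) {
          # re-match on the deprotected structure
          rr <- match_building_blocks(rule, list(dp$mol), policy,
                                      ruleset = ruleset)
          if (length(rr$records) != 1L ||
              rr$records[[1]]$pattern_side != rec$pattern_side) {
            exclusions <- rbind(exclusions,
              data.frame(bb_id = rec$bb$source_id,
                         transform_id = rule$transform_id,
                         variant_tag = rule$variant_tag,
                         reason = "multi_match"))
            next
          }
          rec <- rr$records[[1]]
        }
      }
      mv <- prepare_masked_variants(rec, rule)
      sig <- evaluate_kills(mv, ruleset, rec$pattern_side, rule)
      if (sig$killed) {
        first_kill <- NA_integer_
        for (p in sig$paths) {
          if (identical(p[[length(p)]], "KILL")) {
            first_kill <- p[[length(p) - 1L]]$index; break
          }
        }
        exclusions <- rbind(exclusions,
          data.frame(bb_id = rec$bb$source_id,
                     transform_id = rule$transform_id,
                     variant_tag = rule$variant_tag,
                     reason = paste0("killed:", first_kill)))
        next
      }
      assigned[[k]] <- rule$variant_tag
      s <- rec$pattern_side
      sides[[s]] <- c(sides[[s]], list(list(record = rec, variants = mv,
                                            signature = sig)))
    }
    if (length(rule$reactant_patterns) == 2L) {
      subreactions <- c(subreactions,
                        split_subreactions(rule, sides[[1]], sides[[2]],
                                           ruleset))
    }
  }
  attr(subreactions, "exclusions") <- exclusions
  subreactions
}
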