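# Translated KILL rulesets: loading/validation of the JSON schema, and
# the masked, path-aware evaluation on prepared reactants.
#
# Schema (bit-exact):
# {"transform": int,
#  "statements": [{"index": int, "smarts": [str],
#                  "scope": "ONPATH"|"OFFPATH",
#                  "participants": [int], "goto": int|null}],
#  "untranslatable": [str]}
#
# Statement SMARTS reference mapped reaction atoms through the isotope
# label offset (map number + 100) that the masking step writes into the
# reactant; a statement whose SMARTS carry labels of both reactants is a
# cross-reactant statement, resolved at pairing time.

.KILL_ISO_OFFSET <- 100L

#' Load a translated KILL ruleset
#'
#' Validates the JSON schema, compiles every SMARTS, resolves GOTO
#' targets, and records untranslatable keyword markers (statements with
#' an empty SMARTS list are skip-with-warning entries).
#'
#' @param path path to a ruleset JSON file, or an already-parsed list of
#'   the same shape.
#' @return An object of class `ss_kill_ruleset`.
#' @export
load_kill_ruleset <- function(path) {
  dat <- if (is.character(path)) jsonlite::read_json(path, simplifyVector = FALSE)
         else path
  if (is.null(dat$transform)) stop("KILL ruleset: missing 'transform'")
  stmts <- dat$statements
  if (is.null(stmts)) stmts <- list()
  indices <- vapply(stmts, function(s) as.integer(s$index), 0L)
  if (anyDuplicated(indices)) stop("KILL ruleset: duplicate statement indices")
  if (is.unsorted(indices)) stop("KILL ruleset: statement indices not ordered")
  parsed <- vector("list", length(stmts))
  for (t in seq_along(stmts)) {
    s <- stmts[[t]]
    scope <- s$scope
    if (!(scope %in% c("ONPATH", "OFFPATH")))
      stop("KILL ruleset: bad scope '", scope, "' at index ", s$index)
    sm <- unlist(s$smarts)
    if (is.null(sm)) sm <- character()
    pats <- lapply(sm, parse_smarts)  # errors loudly on bad SMARTS
    gt <- s$goto
    gt <- if (is.null(gt)) NA_integer_ else as.integer(gt)
    if (!is.na(gt) && !(gt %in% indices))
      stop("KILL ruleset: GOTO target ", gt, " at index ", s$index,
           " does not exist")
    parts <- as.integer(unlist(s$participants))
    if (is.null(parts)) parts <- integer()
    parsed[[t]] <- list(index = as.integer(s$index), smarts = sm,
                        patterns = pats, scope = scope,
                        participants = parts, goto = gt,
                        entry_labels = lapply(pats, smarts_iso_labels))
  }
  structure(list(transform_id = as.integer(dat$transform),
                 statements = parsed,
                 untranslatable = as.character(unlist(dat$untranslatable))),
            class = "ss_kill_ruleset")
}

#' @export
print.ss_kill_ruleset <- function(x, ...) {
  cat(sprintf("<KILL ruleset for transform %d: %d statements%s>\n",
              x$transform_id, length(x$statements),
              if (length(x$untranslatable))
                paste0(", untranslatable: ",
                       paste(x$untranslatable, collapse = ",")) else ""))
  invisible(x)
}

# map numbers referenced by a compiled SMARTS through isotope labels
smarts_iso_labels <- function(pattern) {
  labs <- integer()
  walk <- function(e) {
    if (e$node == "prim") {
      if (e$kind == "isotope" && e$num > .KILL_ISO_OFFSET)
        labs <<- c(labs, e$num - .KILL_ISO_OFFSET)
      if (e$kind == "recursive") {
        for (a in e$pattern$atoms) walk(a$expr)
      }
      return(invisible())
    }
    if (e$node == "not") walk(e$arg)
    else for (a in e$args) walk(a)
  }
  for (a in pattern$atoms) walk(a$expr)
  sort(unique(labs))
}

# sides touched by each entry / by the whole statement under a rule
statement_sides <- function(stmt, side_of_map) {
  entry_sides <- lapply(stmt$entry_labels, function(labs) {
    s <- unique(unname(side_of_map[as.character(labs)]))
    s[!is.na(s)]
  })
  part_sides <- unique(unname(side_of_map[as.character(stmt$participants)]))
  part_sides <- part_sides[!is.na(part_sides)]
  all_sides <- unique(c(unlist(entry_sides), part_sides))
  if (!length(all_sides)) all_sides <- c(1L, 2L)  # ANYWHERE statement
  list(entry_sides = entry_sides, sides = sort(all_sides))
}

# Local (one-reactant) outcome of one statement on masked variants:
# ONPATH entries run on variant_a, OFFPATH on variant_b. Only entries
# whose labels touch `side` (or are unlabelled) are consulted.
statement_local <- function(stmt, info, variants, side, ctx_a, ctx_b) {
  hit <- FALSE
  consulted <- FALSE
  for (t in seq_along(stmt$patterns)) {
    es <- info$entry_sides[[t]]
    if (length(es) && !(side %in% es)) next
    consulted <- TRUE
    ctx <- if (stmt$scope == "ONPATH") ctx_a else ctx_b
    if (length(smarts_match_ctx(stmt$patterns[[t]], ctx, first_only = TRUE))) {
      hit <- TRUE
      break
    }
  }
  if (!consulted) NA else hit
}

#' Evaluate KILL statements on one masked reactant
#'
#' Walks the statements in index order: a triggered statement with a
#' GOTO jumps there; a triggered statement without one is a KILL verdict.
#' Statements that depend on the other reactant cannot be resolved and
#' branch the traversal; the result is the nested list of possible paths
#' (the reactant's KILL-path signature). A reactant is `KILLED` only when
#' every branch reaches a KILL verdict. Untranslatable (empty-SMARTS)
#' statements never trigger and are recorded as skipped.
#'
#' @param variants a `ss_masked_variants` object from
#'   [prepare_masked_variants()].
#' @param ruleset an `ss_kill_ruleset`.
#' @param side which reactant side (1 or 2) this reactant matched.
#' @param rule the `ss_reaction_rule` (provides the map-to-side table).
#' @return An object of class `ss_kill_signature` with fields `killed`,
#'   `paths` (list of lists of `(index, triggered)` pairs), `local`
#'   (named logical per statement, `NA` = other-side-dependent) and
#'   `skipped` (indices of untranslatable statements encountered).
#' @export
evaluate_kills <- function(variants, ruleset, side, rule) {
  stmts <- ruleset$statements
  side_of_map <- rule$side_of_map
  ctx_a <- mol_context(variants$variant_a)
  ctx_b <- mol_context(variants$variant_b)
  n <- length(stmts)
  if (!n) {
    return(structure(list(killed = FALSE, paths = list(list()),
                          local = logical(), skipped = integer()),
                     class = "ss_kill_signature"))
  }
  infos <- lapply(stmts, statement_sides, side_of_map = side_of_map)
  indices <- vapply(stmts, `[[`, 0L, "index")
  local <- rep(NA, n)
  skipped <- integer()
  for (t in seq_len(n)) {
    if (!length(stmts[[t]]$patterns)) {
      skipped <- c(skipped, indices[t])
      local[t] <- FALSE  # untranslatable: never triggers, logged
      next
    }
    local[t] <- statement_local(stmts[[t]], infos[[t]], variants, side,
                                ctx_a, ctx_b)
  }
  names(local) <- indices
  # possible trigger values for this reactant alone
  trigger_options <- function(t) {
    info <- infos[[t]]
    if (!length(stmts[[t]]$patterns)) return(FALSE)
    cross_and <- length(info$sides) == 2L &&
      any(vapply(info$entry_sides, function(e) 1L %in% e, TRUE)) &&
      any(vapply(info$entry_sides, function(e) 2L %in% e, TRUE))
    lv <- unname(local[t])
    if (cross_and) {
      # conjunction across sides: FALSE locally decides; TRUE leaves it
      # to the partner
      if (isFALSE(lv)) FALSE else c(TRUE, FALSE)
    } else if (identical(info$sides, side)) {
      if (is.na(lv)) c(TRUE, FALSE) else lv  # purely this side: decided
    } else if (side %in% info$sides) {
      # disjunction (ANYWHERE) or shared: TRUE decides, FALSE branches
      if (isTRUE(lv)) TRUE else c(TRUE, FALSE)
    } else {
      c(TRUE, FALSE)  # other side only: branch point
    }
  }
  paths <- list()
  any_survive <- FALSE
  walk <- function(t, acc) {
    if (t > n) {
      paths[[length(paths) + 1L]] <<- acc
      any_survive <<- TRUE
      return(invisible())
    }
    for (tr in trigger_options(t)) {
      step <- c(acc, list(list(index = indices[t], triggered = tr)))
      if (tr) {
        gt <- stmts[[t]]$goto
        if (is.na(gt)) {
          paths[[length(paths) + 1L]] <<- c(step, list("KILL"))
        } else {
          walk(match(gt, indices), step)
        }
      } else {
        walk(t + 1L, step)
      }
    }
  }
  walk(1L, list())
  structure(list(killed = !any_survive, paths = paths, local = local,
                 skipped = skipped),
            class = "ss_kill_signature")
}

#' @export
print.ss_kill_signature <- function(x, ...) {
  cat(sprintf("<kill signature: %s, %d path(s)%s>\n",
              if (x$killed) "KILLED" else "survives", length(x$paths),
              if (length(x$skipped))
                paste0(", skipped ", paste(x$skipped, collapse = ",")) else ""))
  invisible(x)
}

signature_key <- function(sig) {
  paste(ifelse(is.na(sig$local), "x", ifelse(sig$local, "1", "0")),
        collapse = "")
}

# Pair-level verdict: with both sides' local outcomes every statement is
# decided; walk the statement list with GOTO jumps and report KILL or
# survive. Used by the sub-reaction splitter and by the product-level
# comparison tests.
pair_killed <- function(sig1, sig2, ruleset, rule) {
  stmts <- ruleset$statements
  n <- length(stmts)
  if (!n) return(FALSE)
  side_of_map <- rule$side_of_map
  infos <- lapply(stmts, statement_sides, side_of_map = side_of_map)
  indices <- vapply(stmts, `[[`, 0L, "index")
  t <- 1L
  guard <- 0L
  while (t <= n) {
    guard <- guard + 1L
    if (guard > 10L * n) stop("KILL traversal did not terminate (GOTO loop?)")
    info <- infos[[t]]
    l1 <- sig1$local[t]; l2 <- sig2$local[t]
    cross_and <- length(info$sides) == 2L &&
      any(vapply(info$entry_sides, function(e) 1L %in% e, TRUE)) &&
      any(vapply(info$entry_sides, function(e) 2L %in% e, TRUE))
    tr <- if (cross_and) {
      isTRUE(l1) && isTRUE(l2)
    } else {
      isTRUE(l1) || isTRUE(l2)
    }
    if (tr) {
      gt <- stmts[[t]]$goto
      if (is.na(gt)) return(TRUE)
      t <- match(gt, indices)
    } else {
      t <- t + 1L
    }
  }
  FALSE
}

#' SMARTS alternatives for a same-ring constraint
#'
#' "in the same ring as" has no direct SMARTS counterpart: every possible
#' ring-bond distance between the two atoms must be queried. This helper
#' enumerates the alternatives up to a maximum of six ring bonds.
#'
#' @param anchor_a,anchor_b SMARTS atom expressions for the two atoms
#'   (including brackets).
#' @param max_bonds maximum ring-bond path length (default 6).
#' @return Character vector of SMARTS, one per distance.
#' @export
#' @examples
#' kill_same_ring_smarts("[102*]", "[#7;R]", 3)
kill_same_ring_smarts <- function(anchor_a, anchor_b, max_bonds = 6L) {
  vapply(seq_len(max_bonds), function(k) {
    paste0(anchor_a, strrep("@[*;R]", k - 1L), "@", anchor_b)
  }, "")
}
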