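# SMARTS-subset parser and substructure matcher.
#
# Supported atom primitives: element symbols (aliphatic/aromatic), #n
# atomic number (aromaticity-neutral), * wildcard, a/A, Hn implicit-H
# count, Dn degree, Xn total connectivity, R/Rn ring-membership count,
# r/rn ring size, +/- charges, isotope numbers (used for synthon map
# labels), recursive $(...) environments, and atom maps :n. Logical
# operators !, & (or juxtaposition), ',' and ';' with Daylight precedence.
# Bond primitives: - = # : ~ @ with the same logical operators; an omitted
# bond is single-or-aromatic.
#
# Mask semantics: dummy atoms ("*" element, atomic number 0) in a molecule
# are matchable only by pattern atoms that positively mention #0. In
# particular negations like [!#6] do NOT match a mask atom, so KILL
# patterns can never reach into a masked leaving group or a cut backbone.

#' Parse a SMARTS pattern
#'
#' @param smarts pattern string (single component, no `>>`).
#' @return An object of class `ss_smarts` with `atoms` (expression trees +
#'   atom maps) and `bonds`.
#' @export
#' @examples
#' p <- parse_smarts("[C;H2][NX3]")
parse_smarts <- function(smarts) {
  s <- gsub("[[:space:]]", "", smarts)
  if (!nzchar(s)) stop("empty SMARTS")
  atoms <- list()
  bonds <- list()
  pos <- 1L; nchr <- nchar(s)
  prev <- 0L
  pending <- NULL
  stack <- integer()
  ring_open <- list()
  bond_chars <- c("-", "=", "#", ":", "~", "@", "!", ",", ";", "&")
  add_atom <- function(expr, map) {
    atoms[[length(atoms) + 1L]] <<- list(expr = expr, map = map)
    length(atoms)
  }
  add_bond <- function(i, j, expr) {
    bonds[[length(bonds) + 1L]] <<- list(a1 = i, a2 = j, expr = expr)
  }
  scan_bond <- function() {
    # maximal run of bond chars, stopping before "#<digit>" (atomic number)
    start <- pos
    while (pos <= nchr) {
      ch <- substr(s, pos, pos)
      if (!(ch %in% bond_chars)) break
      if (ch == "#" && grepl("^[0-9]", substr(s, pos + 1L, pos + 1L))) {
        # "#" directly before a digit outside brackets is still a triple
        # bond (atomic numbers only occur inside brackets); keep it
      }
      pos <<- pos + 1L
    }
    if (pos == start) return(NULL)
    parse_bond_expr(substr(s, start, pos - 1L))
  }
  connect <- function(idx) {
    if (prev > 0L) {
      expr <- if (is.null(pending)) .default_bond_expr() else pending
      add_bond(prev, idx, expr)
    }
    prev <<- idx
    pending <<- NULL
  }
  while (pos <= nchr) {
    ch <- substr(s, pos, pos)
    if (ch == "(") {
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMARTS: ", smarts)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch %in% bond_chars) {
      pending <- scan_bond()
      ch2 <- substr(s, pos, pos)
      if (grepl("^[0-9%]$", ch2)) next  # ring closure handled below
    } else if (grepl("^[0-9%]$", ch)) {
      if (ch == "%") { digit <- substr(s, pos + 1L, pos + 2L); pos <- pos + 3L }
      else { digit <- ch; pos <- pos + 1L }
      if (prev == 0L) stop("ring closure before any atom in SMARTS: ", smarts)
      if (!is.null(ring_open[[digit]])) {
        op <- ring_open[[digit]]
        expr <- if (!is.null(pending)) pending
                else if (!is.null(op$expr)) op$expr
                else .default_bond_expr()
        add_bond(op$atom, prev, expr)
        ring_open[[digit]] <- NULL
      } else {
        ring_open[[digit]] <- list(atom = prev, expr = pending)
      }
      pending <- NULL
    } else if (ch == "[") {
      end <- find_bracket_end(s, pos)
      body <- substr(s, pos + 1L, end - 1L)
      pos <- end + 1L
      at <- parse_smarts_bracket(body)
      idx <- add_atom(at$expr, at$map)
      connect(idx)
    } else {
      at <- scan_plain_atom(s, pos)
      if (is.null(at)) stop("unexpected character '", ch, "' at position ",
                            pos, " in SMARTS: ", smarts)
      pos <- pos + at$width
      idx <- add_atom(at$expr, 0L)
      connect(idx)
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMARTS: ", smarts)
  open <- names(ring_open)[!vapply(ring_open, is.null, TRUE)]
  if (length(open)) stop("unclosed ring bond(s) ", paste(open, collapse = ","),
                         " in SMARTS: ", smarts)
  nb <- length(bonds)
  bdf <- data.frame(a1 = vapply(bonds, `[[`, 0L, "a1"),
                    a2 = vapply(bonds, `[[`, 0L, "a2"))
  structure(list(atoms = atoms,
                 bonds = bdf,
                 bond_exprs = lapply(bonds, `[[`, "expr"),
                 source = smarts),
            class = "ss_smarts")
}

#' @export
print.ss_smarts <- function(x, ...) {
  cat(sprintf("<SMARTS %s: %d atoms, %d bonds>\n", x$source,
              length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# position of the ']' closing the '[' at `pos`, respecting $(...) nesting
find_bracket_end <- function(s, pos) {
  depth_par <- 0L
  i <- pos + 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") depth_par <- depth_par + 1L
    else if (ch == ")") depth_par <- depth_par - 1L
    else if (ch == "]" && depth_par == 0L) return(i)
    i <- i + 1L
  }
  stop("unterminated bracket atom in SMARTS")
}

.TWO_LETTER <- c("Cl", "Br", "Si", "Se", "Na", "Mg", "Li", "Ca", "Fe",
                 "Cu", "Zn", "Sn", "Al", "Pd", "Pt", "Ag", "Au", "Hg",
                 "Mn", "Ni", "Co", "Cr", "Ti", "As", "Sb", "Bi", "Pb")

scan_plain_atom <- function(s, pos) {
  two <- substr(s, pos, pos + 1L)
  if (two %in% .TWO_LETTER) {
    return(list(expr = prim("element", symbol = two, aromatic = FALSE),
                width = 2L))
  }
  ch <- substr(s, pos, pos)
  if (ch == "*") return(list(expr = prim("wildcard"), width = 1L))
  if (ch == "a") return(list(expr = prim("arom_any"), width = 1L))
  if (ch == "A") return(list(expr = prim("aliph_any"), width = 1L))
  if (grepl("^[BCNOPSFI]$", ch)) {
    return(list(expr = prim("element", symbol = ch, aromatic = FALSE),
                width = 1L))
  }
  if (grepl("^[bcnops]$", ch)) {
    return(list(expr = prim("element", symbol = toupper(ch), aromatic = TRUE),
                width = 1L))
  }
  NULL
}

prim <- function(kind, ...) c(list(node = "prim", kind = kind), list(...))

.default_bond_expr <- function() list(node = "prim", kind = "single_or_arom")

# --- bracket atom expression parser -----------------------------------

parse_smarts_bracket <- function(body) {
  map <- 0L
  m <- regmatches(body, regexpr(":[0-9]+$", body))
  if (length(m)) {
    map <- as.integer(substring(m, 2L))
    body <- sub(":[0-9]+$", "", body)
  }
  env <- new.env(parent = emptyenv())
  env$s <- body; env$pos <- 1L; env$n <- nchar(body)
  expr <- parse_expr_low(env)
  if (env$pos <= env$n) {
    stop("unparsed SMARTS atom expression remainder: '",
         substr(env$s, env$pos, env$n), "' in [", body, "]")
  }
  list(expr = expr, map = map)
}

peek <- function(env) if (env$pos > env$n) "" else substr(env$s, env$pos, env$pos)
advance <- function(env, k = 1L) env$pos <- env$pos + k

parse_expr_low <- function(env) {          # ';' = lowest AND
  terms <- list(parse_expr_or(env))
  while (peek(env) == ";") { advance(env); terms <- c(terms, list(parse_expr_or(env))) }
  if (length(terms) == 1L) terms[[1]] else list(node = "and", args = terms)
}
parse_expr_or <- function(env) {           # ','
  terms <- list(parse_expr_and(env))
  while (peek(env) == ",") { advance(env); terms <- c(terms, list(parse_expr_and(env))) }
  if (length(terms) == 1L) terms[[1]] else list(node = "or", args = terms)
}
parse_expr_and <- function(env) {          # '&' or juxtaposition
  terms <- list(parse_factor(env))
  repeat {
    ch <- peek(env)
    if (ch == "&") { advance(env); terms <- c(terms, list(parse_factor(env))) }
    else if (ch != "" && !(ch %in% c(";", ",", ")")))
      terms <- c(terms, list(parse_factor(env)))
    else break
  }
  if (length(terms) == 1L) terms[[1]] else list(node = "and", args = terms)
}
parse_factor <- function(env) {
  ch <- peek(env)
  if (ch == "!") { advance(env); return(list(node = "not", arg = parse_factor(env))) }
  parse_primitive(env)
}

read_digits <- function(env) {
  start <- env$pos
  while (grepl("^[0-9]$", peek(env))) advance(env)
  if (env$pos == start) return(NA_integer_)
  as.integer(substr(env$s, start, env$pos - 1L))
}

parse_primitive <- function(env) {
  ch <- peek(env)
  if (ch == "$") {
    advance(env)
    if (peek(env) != "(") stop("expected '(' after '$' in recursive SMARTS")
    depth <- 0L; start <- env$pos
    repeat {
      c2 <- peek(env)
      if (c2 == "") stop("unterminated recursive SMARTS")
      if (c2 == "(") depth <- depth + 1L
      if (c2 == ")") { depth <- depth - 1L
        if (depth == 0L) break }
      advance(env)
    }
    inner <- substr(env$s, start + 1L, env$pos - 1L)
    advance(env)
    return(prim("recursive", pattern = parse_smarts(inner)))
  }
  if (ch == "#") {
    advance(env)
    num <- read_digits(env)
    if (is.na(num)) stop("expected atomic number after '#'")
    return(prim("atomnum", num = num))
  }
  if (grepl("^[0-9]$", ch)) {
    return(prim("isotope", num = read_digits(env)))
  }
  if (ch == "*") { advance(env); return(prim("wildcard")) }
  if (ch == "@") { advance(env); while (peek(env) == "@") advance(env)
    return(prim("wildcard")) }  # stereo ignored
  if (ch == "+") {
    advance(env)
    k <- 1L
    while (peek(env) == "+") { advance(env); k <- k + 1L }
    num <- read_digits(env)
    return(prim("charge", num = if (!is.na(num)) num else k))
  }
  if (ch == "-") {
    advance(env)
    k <- 1L
    while (peek(env) == "-") { advance(env); k <- k + 1L }
    num <- read_digits(env)
    return(prim("charge", num = -(if (!is.na(num)) num else k)))
  }
  if (ch == "H") { advance(env); num <- read_digits(env)
    return(prim("hcount", num = if (is.na(num)) 1L else num)) }
  if (ch == "D") { advance(env); num <- read_digits(env)
    return(prim("degree", num = if (is.na(num)) 1L else num)) }
  if (ch == "X") { advance(env); num <- read_digits(env)
    return(prim("connectivity", num = if (is.na(num)) 1L else num)) }
  if (ch == "R") { advance(env); num <- read_digits(env)
    return(prim("ringcount", num = num)) }
  if (ch == "r") { advance(env); num <- read_digits(env)
    return(prim("ringsize", num = num)) }
  if (ch == "a") { advance(env); return(prim("arom_any")) }
  if (ch == "A") { advance(env); return(prim("aliph_any")) }
  two <- substr(env$s, env$pos, env$pos + 1L)
  if (two %in% .TWO_LETTER) { advance(env, 2L)
    return(prim("element", symbol = two, aromatic = FALSE)) }
  if (grepl("^[A-Z]$", ch)) { advance(env)
    return(prim("element", symbol = ch, aromatic = FALSE)) }
  if (grepl("^[bcnops]$", ch)) { advance(env)
    return(prim("element", symbol = toupper(ch), aromatic = TRUE)) }
  stop("cannot parse SMARTS atom primitive at '",
       substr(env$s, env$pos, env$n), "'")
}

parse_bond_expr <- function(txt) {
  env <- new.env(parent = emptyenv())
  env$s <- txt; env$pos <- 1L; env$n <- nchar(txt)
  expr <- parse_bexpr_low(env)
  if (env$pos <= env$n) stop("unparsed bond expression: '", txt, "'")
  expr
}
parse_bexpr_low <- function(env) {
  terms <- list(parse_bexpr_or(env))
  while (peek(env) == ";") { advance(env); terms <- c(terms, list(parse_bexpr_or(env))) }
  if (length(terms) == 1L) terms[[1]] else list(node = "and", args = terms)
}
parse_bexpr_or <- function(env) {
  terms <- list(parse_bexpr_and(env))
  while (peek(env) == ",") { advance(env); terms <- c(terms, list(parse_bexpr_and(env))) }
  if (length(terms) == 1L) terms[[1]] else list(node = "or", args = terms)
}
parse_bexpr_and <- function(env) {
  terms <- list(parse_bfactor(env))
  repeat {
    ch <- peek(env)
    if (ch == "&") { advance(env); terms <- c(terms, list(parse_bfactor(env))) }
    else if (ch %in% c("-", "=", "#", ":", "~", "@", "!"))
      terms <- c(terms, list(parse_bfactor(env)))
    else break
  }
  if (length(terms) == 1L) terms[[1]] else list(node = "and", args = terms)
}
parse_bfactor <- function(env) {
  ch <- peek(env)
  if (ch == "!") { advance(env); return(list(node = "not", arg = parse_bfactor(env))) }
  advance(env)
  switch(ch,
    "-" = prim("bond_single"),
    "=" = prim("bond_double"),
    "#" = prim("bond_triple"),
    ":" = prim("bond_aromatic"),
    "~" = prim("bond_any"),
    "@" = prim("bond_ring"),
    stop("unknown bond primitive '", ch, "'"))
}

# --- evaluation --------------------------------------------------------

# Precomputed per-molecule match context.
mol_context <- function(mol) {
  mol <- with_rings(mol)
  n <- n_atoms(mol)
  deg <- integer(n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    deg[b$a2[k]] <- deg[b$a2[k]] + 1L
  }
  rings <- mol_rings(mol)
  ringcnt <- integer(n)
  ringsizes <- vector("list", n)
  for (r in rings) {
    ringcnt[r] <- ringcnt[r] + 1L
    for (i in r) ringsizes[[i]] <- c(ringsizes[[i]], length(r))
  }
  list(mol = mol, deg = deg, ringcnt = ringcnt, ringsizes = ringsizes,
       elnum = element_number(mol$atoms$element), adj = mol_adj(mol))
}

expr_mentions_atomnum0 <- function(expr) {
  if (expr$node == "prim") {
    return(expr$kind == "atomnum" && expr$num == 0L)
  }
  if (expr$node == "not") return(FALSE)
  any(vapply(expr$args, expr_mentions_atomnum0, TRUE))
}

eval_atom_expr <- function(expr, ctx, a) {
  mol <- ctx$mol
  if (mol$atoms$element[a] == "*") {
    # mask semantics: dummies match only patterns positively naming #0
    return(expr_mentions_atomnum0(expr))
  }
  eval_node <- function(e) {
    switch(e$node,
      "and" = all(vapply(e$args, eval_node, TRUE)),
      "or"  = any(vapply(e$args, eval_node, TRUE)),
      "not" = !eval_node(e$arg),
      "prim" = eval_prim(e),
      stop("bad expression node"))
  }
  eval_prim <- function(e) {
    switch(e$kind,
      wildcard = TRUE,
      arom_any = mol$atoms$aromatic[a],
      aliph_any = !mol$atoms$aromatic[a],
      element = mol$atoms$element[a] == e$symbol &&
                mol$atoms$aromatic[a] == e$aromatic,
      atomnum = ctx$elnum[a] == e$num,
      isotope = mol$atoms$isotope[a] == e$num,
      hcount = mol$atoms$nH[a] == e$num,
      degree = ctx$deg[a] == e$num,
      connectivity = ctx$deg[a] + mol$atoms$nH[a] == e$num,
      ringcount = if (is.na(e$num)) ctx$ringcnt[a] >= 1L
                  else ctx$ringcnt[a] == e$num,
      ringsize = if (is.na(e$num)) ctx$ringcnt[a] >= 1L
                 else e$num %in% ctx$ringsizes[[a]],
      charge = mol$atoms$charge[a] == e$num,
      recursive = length(smarts_match_ctx(e$pattern, ctx, root = a,
                                          first_only = TRUE)) > 0L,
      stop("unknown atom primitive kind: ", e$kind))
  }
  eval_node(expr)
}

eval_bond_expr <- function(expr, ctx, k) {
  b <- ctx$mol$bonds
  eval_node <- function(e) {
    switch(e$node,
      "and" = all(vapply(e$args, eval_node, TRUE)),
      "or"  = any(vapply(e$args, eval_node, TRUE)),
      "not" = !eval_node(e$arg),
      "prim" = switch(e$kind,
        bond_single = b$order[k] == 1L && !b$aromatic[k],
        bond_double = b$order[k] == 2L && !b$aromatic[k],
        bond_triple = b$order[k] == 3L,
        bond_aromatic = b$aromatic[k],
        bond_any = TRUE,
        bond_ring = b$ring[k],
        single_or_arom = (b$order[k] == 1L && !b$aromatic[k]) || b$aromatic[k],
        stop("unknown bond primitive kind: ", e$kind)),
      stop("bad bond expression node"))
  }
  eval_node(expr)
}

# --- subgraph matcher --------------------------------------------------

# Matching order: pattern atoms reordered so each (after the first) touches
# an earlier one; patterns are connected by construction.
pattern_order <- function(pat) {
  np <- length(pat$atoms)
  if (np == 0L) stop("empty pattern")
  order <- 1L
  remaining <- setdiff(seq_len(np), order)
  while (length(remaining)) {
    nxt <- NA_integer_
    for (q in remaining) {
      touches <- any((pat$bonds$a1 == q & pat$bonds$a2 %in% order) |
                     (pat$bonds$a2 == q & pat$bonds$a1 %in% order))
      if (touches) { nxt <- q; break }
    }
    if (is.na(nxt)) nxt <- remaining[1]  # disconnected pattern: new seed
    order <- c(order, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  order
}

smarts_match_ctx <- function(pat, ctx, root = NULL, first_only = FALSE,
                             uniquify = "none") {
  np <- length(pat$atoms)
  nm <- n_atoms(ctx$mol)
  if (nm == 0L) return(list())
  ord <- pattern_order(pat)
  # bonds to check when placing the t-th pattern atom (to earlier atoms)
  placed_at <- integer(np); placed_at[ord] <- seq_len(np)
  checks <- vector("list", np)
  for (k in seq_len(nrow(pat$bonds))) {
    i <- pat$bonds$a1[k]; j <- pat$bonds$a2[k]
    ti <- placed_at[i]; tj <- placed_at[j]
    later <- max(ti, tj)
    checks[[later]] <- c(checks[[later]],
                         list(list(other = if (later == ti) j else i, bond = k)))
  }
  results <- list()
  assign <- integer(np)  # pattern idx -> mol atom
  used <- logical(nm)
  bt <- function(t) {
    if (t > np) {
      results[[length(results) + 1L]] <<- assign
      return(first_only)
    }
    p <- ord[t]
    cands <- if (t == 1L && !is.null(root)) root
             else if (t == 1L || !length(checks[[t]])) seq_len(nm)
             else {
               # adjacency-driven candidates
               anchor <- checks[[t]][[1]]
               ctx$adj[[assign[anchor$other]]]$nbr
             }
    for (m in cands) {
      if (used[m]) next
      if (!eval_atom_expr(pat$atoms[[p]]$expr, ctx, m)) next
      ok <- TRUE
      for (chk in checks[[t]]) {
        kb <- bond_between(ctx$mol, m, assign[chk$other])
        if (!length(kb) || !eval_bond_expr(pat$bond_exprs[[chk$bond]], ctx, kb[1])) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      assign[p] <<- m; used[m] <<- TRUE
      done <- bt(t + 1L)
      assign[p] <<- 0L; used[m] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  bt(1L)
  if (uniquify == "atoms" && length(results) > 1L) {
    keys <- vapply(results, function(x) paste(sort(x), collapse = ","), "")
    results <- results[!duplicated(keys)]
  }
  results
}

#' Match a SMARTS pattern against a molecule
#'
#' @param mol an `ss_mol` (aromaticity should be perceived first so aromatic
#'   primitives behave under the intended model).
#' @param pattern an `ss_smarts` from [parse_smarts()], or a pattern string.
#' @param uniquify `"none"` returns every embedding; `"atoms"` collapses
#'   embeddings covering the same atom set (the match-unification used by
#'   the LIB2020 duplicate policy).
#' @return List of integer vectors, each mapping pattern atom index to
#'   molecule atom index.
#' @export
#' @examples
#' smarts_match(parse_smiles("CCO"), "[C][O;H1]")
smarts_match <- function(mol, pattern, uniquify = c("none", "atoms")) {
  uniquify <- match.arg(uniquify)
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  ctx <- mol_context(mol)
  smarts_match_ctx(pattern, ctx, uniquify = uniquify)
}

#' Does a molecule contain a SMARTS pattern?
#'
#' @inheritParams smarts_match
#' @return `TRUE` or `FALSE`.
#' @export
smarts_has_match <- function(mol, pattern) {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  ctx <- mol_context(mol)
  length(smarts_match_ctx(pattern, ctx, first_only = TRUE)) > 0L
}

# Matches keyed by pattern atom-map numbers: list of named integer vectors
# (names = map numbers as character), one per embedding.
smarts_match_mapped <- function(mol, pattern, uniquify = "none") {
  if (is.character(pattern)) pattern <- parse_smarts(pattern)
  maps <- vapply(pattern$atoms, `[[`, 0L, "map")
  res <- smarts_match(mol, pattern, uniquify = uniquify)
  lapply(res, function(x) {
    v <- x[maps > 0L]
    names(v) <- maps[maps > 0L]
    v
  })
}
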