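# Pattern-graph to SMARTS translation: atom/bond keyword mapping, range
# enumeration, functional-group recursion, fusion-bond variant expansion,
# and whole-transform translation to reaction rules.

.tmap_cache <- new.env(parent = emptyenv())

#' Load the keyword-to-SMARTS translation map
#'
#' @param path optional path to a map JSON; defaults to the bundled map.
#' @return Translation map as a list.
#' @export
translation_map <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.tmap_cache$m)) return(.tmap_cache$m)
    path <- system.file("extdata", "translation_map.json",
                        package = "synthonspace", mustWork = FALSE)
    if (!nzchar(path) || !file.exists(path))
      path <- file.path("inst", "extdata", "translation_map.json")
    m <- jsonlite::read_json(path, simplifyVector = FALSE)
    m$bonds <- unlist(m$bonds)
    .tmap_cache$m <- m
    return(m)
  }
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  m$bonds <- unlist(m$bonds)
  m
}

hs_annotation <- function(op, n, cap = 4L) {
  n <- as.integer(n)
  vals <- switch(op,
    "=" = n,
    ">" = if (n + 1L > cap) integer() else seq(n + 1L, cap),
    "<" = if (n < 1L) integer() else seq(0L, n - 1L))
  if (!length(vals))
    stop("hydrogen-count range ", op, n, " is empty under enumeration cap ", cap)
  paste(paste0("H", vals), collapse = ",")
}

hets_pos <- function(k, het = "[!#6;!#1]") {
  paste0("$([*]", strrep(paste0("(~", het, ")"), k), ")")
}

hets_annotation <- function(op, n, cap = 4L, het = "[!#6;!#1]") {
  n <- as.integer(n)
  switch(op,
    "=" = if (n == 0L) paste0("!", hets_pos(1L, het))
          else if (n >= cap) hets_pos(n, het)
          else paste0(hets_pos(n, het), ";!", hets_pos(n + 1L, het)),
    ">" = hets_pos(min(n + 1L, cap), het),
    "<" = if (n < 1L) stop("HETS<0 is empty") else paste0("!", hets_pos(n, het)))
}

fgs_annotation <- function(args, negated, map) {
  groups <- map$functional_groups
  templates <- character()
  for (g in args) {
    entry <- groups[[g]]
    if (is.null(entry))
      stop("unknown functional group keyword '", g, "' in translation map")
    templates <- c(templates, unlist(entry$smarts))
  }
  wrapped <- paste0("$(", templates, ")")
  if (negated) paste(paste0("!", wrapped), collapse = ";")
  else paste(wrapped, collapse = ",")
}

#' Translate a pattern node to a SMARTS atom expression
#'
#' Combines the element (emitted as an aromaticity-neutral atomic-number
#' primitive unless an AROMATIC/ALIPHATIC property constrains it), the
#' property translations (exact or enumerated H counts, neighbouring
#' heteroatom counts via recursive environments, functional-group
#' presence joined with OR / absence with AND of negations, charge, ring
#' membership) and the atom map.
#'
#' @param node a node from an `ss_pattern_graph`.
#' @param map translation map from [translation_map()].
#' @param grammar grammar from [patran_grammar()] (element name table and
#'   range-enumeration cap).
#' @param side `"reactant"` or `"product"` (products allow only H-count
#'   and aromaticity properties).
#' @param map_number atom map to emit (`NA` for none).
#' @return SMARTS atom expression string, e.g. `"[#6;H2:1]"`.
#' @export
translate_atom <- function(node, map = translation_map(),
                           grammar = patran_grammar(),
                           side = c("reactant", "product"),
                           map_number = node$map_number) {
  side <- match.arg(side)
  element <- grammar$atoms[[node$atom_text]]
  if (is.null(element))
    stop("unknown atom keyword '", node$atom_text, "'")
  cap <- if (!is.null(grammar$range_cap)) as.integer(grammar$range_cap) else 4L
  base <- if (element == "*") "*"
          else paste0("#", element_number(element))
  terms <- base
  for (p in node$properties) {
    kw <- p$keyword
    if (side == "product" && !(kw %in% c("HS", "AROMATIC")))
      stop("property '", kw, "' is not allowed in a product pattern ",
           "(only hydrogen counts and explicit aromaticity)")
    ann <- switch(kw,
      HS = hs_annotation(p$op, p$args[1], cap),
      HETS = hets_annotation(p$op, p$args[1], cap, map$het_smarts),
      CHARGE = {
        v <- as.integer(gsub("\\+", "", p$args[1]))
        if (v >= 0) paste0("+", v) else as.character(v)
      },
      FGS = fgs_annotation(p$args, p$negated, map),
      AROMATIC = if (p$negated) "A" else "a",
      ALIPHATIC = if (p$negated) "a" else "A",
      RING = if (p$negated) "R0" else "R",
      stop("unknown atom property keyword '", kw, "'"))
    terms <- c(terms, ann)
  }
  extra <- node$extra_annotations
  if (!is.null(extra)) terms <- c(terms, extra)
  body <- paste(terms, collapse = ";")
  if (!is.na(map_number) && !is.null(map_number))
    body <- paste0(body, ":", map_number)
  paste0("[", body, "]")
}

#' Translate a pattern edge to a SMARTS bond expression
#'
#' Bond properties SMARTS can state on bonds (ring membership) are
#' appended to the bond symbol; fusion properties are not handled here —
#' they become adjacent-atom annotations via [expand_fusion_variants()].
#'
#' @param edge an edge from an `ss_pattern_graph`.
#' @param map translation map.
#' @return The SMARTS bond string (possibly `""`-adjacent symbols like
#'   `"-@"`).
#' @export
translate_bond <- function(edge, map = translation_map()) {
  sym <- unname(map$bonds[edge$bond_text])
  if (length(sym) != 1L || is.na(sym))
    stop("unknown bond keyword '", edge$bond_text, "'")
  for (p in edge$properties) {
    keyword <- sub("^!", "", p)
    if (keyword == "FUSION") next  # handled as atom annotations
    entry <- map$bond_properties[[keyword]]
    if (is.null(entry)) stop("unknown bond property '", p, "'")
    if (!is.null(entry$bond_append)) sym <- paste0(sym, entry$bond_append)
  }
  sym
}

#' Expand fusion-bond variants of a pattern graph
#'
#' A positively asserted fusion bond annotates both incident atoms as
#' fusion atoms (in at least two rings). A negated fusion bond cannot be
#' stated on both atoms without contradiction, so the annotation is
#' assigned once to one and, in a duplicated pattern, to the other
#' adjacent atom: each negated-fusion edge doubles the variant count.
#'
#' @param graph an `ss_pattern_graph`.
#' @param map translation map (fusion annotation strings).
#' @return List of variant graphs; each carries a `variant_tag` attribute
#'   (`""` when no negated-fusion edge exists).
#' @export
expand_fusion_variants <- function(graph, map = translation_map()) {
  fus <- map$bond_properties$FUSION
  annotate <- function(g, node_idx0, ann) {
    nd <- g$nodes[[node_idx0 + 1L]]
    nd$extra_annotations <- c(nd$extra_annotations, ann)
    g$nodes[[node_idx0 + 1L]] <- nd
    g
  }
  base <- graph
  neg_edges <- integer()
  for (e in seq_along(graph$edges)) {
    props <- graph$edges[[e]]$properties
    if ("FUSION" %in% props) {
      base <- annotate(base, graph$edges[[e]]$start, fus$atom_annotation)
      base <- annotate(base, graph$edges[[e]]$end, fus$atom_annotation)
    }
    if ("!FUSION" %in% props) neg_edges <- c(neg_edges, e)
  }
  if (!length(neg_edges)) {
    attr(base, "variant_tag") <- ""
    return(list(base))
  }
  variants <- list(base)
  tags <- ""
  for (e in neg_edges) {
    new_variants <- list(); new_tags <- character()
    for (v in seq_along(variants)) {
      ga <- annotate(variants[[v]], graph$edges[[e]]$start,
                     fus$negated_annotation)
      gb <- annotate(variants[[v]], graph$edges[[e]]$end,
                     fus$negated_annotation)
      new_variants <- c(new_variants, list(ga, gb))
      ta <- paste0(tags[v], if (nzchar(tags[v])) "." else "", "e", e, "a")
      tb <- paste0(tags[v], if (nzchar(tags[v])) "." else "", "e", e, "b")
      new_tags <- c(new_tags, ta, tb)
    }
    variants <- new_variants; tags <- new_tags
  }
  for (v in seq_along(variants)) attr(variants[[v]], "variant_tag") <- tags[v]
  variants
}

bond_text_order <- function(txt) {
  switch(txt, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 1L, "~" = 1L, 1L)
}

#' Emit a SMARTS string from a translated pattern graph
#'
#' Iterates the node list in source order; branches are parenthesized by
#' branch level and ring-closure edges become SMARTS ring-bond digits.
#' The output is checked to parse in the package's SMARTS engine.
#'
#' @param graph an `ss_pattern_graph` (optionally fusion-annotated).
#' @param map translation map.
#' @param grammar grammar table.
#' @param side `"reactant"` or `"product"`.
#' @param maps integer vector of atom maps per node (0-based node order);
#'   default uses the nodes' own circumflex maps (reactants) or sequential
#'   order starting at 1 (products).
#' @return A SMARTS string.
#' @export
emit_smarts <- function(graph, map = translation_map(),
                        grammar = patran_grammar(),
                        side = c("reactant", "product"), maps = NULL) {
  side <- match.arg(side)
  nn <- length(graph$nodes)
  if (is.null(maps)) {
    maps <- if (side == "product") seq_len(nn)
            else vapply(graph$nodes, function(n)
              if (is.null(n$map_number)) NA_integer_ else n$map_number, 0L)
  }
  atom_tok <- vapply(seq_len(nn), function(i)
    translate_atom(graph$nodes[[i]], map, grammar, side,
                   map_number = maps[i]), "")
  # sequential tree + ring closures
  children <- vector("list", nn)
  ring_at <- vector("list", nn)
  digit <- 0L
  for (e in graph$edges) {
    bond_str <- translate_bond(e, map)
    # product patterns are matched against perceived products, where a
    # newly formed ring may be aromatic: tolerate the aromatic flag
    if (side == "product" && bond_str %in% c("-", "="))
      bond_str <- paste0(bond_str, ",:")
    if (e$start < e$end) {
      children[[e$start + 1L]] <- c(children[[e$start + 1L]],
                                    list(list(node = e$end, bond = bond_str)))
    } else {
      digit <- digit + 1L
      d <- if (digit > 9L) paste0("%", digit) else as.character(digit)
      tok <- paste0(bond_str, d)
      ring_at[[e$start + 1L]] <- c(ring_at[[e$start + 1L]], tok)
      ring_at[[e$end + 1L]] <- c(ring_at[[e$end + 1L]], tok)
    }
  }
  render <- function(i0) {
    tok <- paste0(atom_tok[i0 + 1L],
                  paste(unlist(ring_at[[i0 + 1L]]), collapse = ""))
    ch <- children[[i0 + 1L]]
    if (!length(ch)) return(tok)
    ch <- ch[order(vapply(ch, `[[`, 0L, "node"))]
    parts <- tok
    for (t in seq_along(ch)) {
      sub <- paste0(ch[[t]]$bond, render(ch[[t]]$node))
      if (t < length(ch)) sub <- paste0("(", sub, ")")
      parts <- c(parts, sub)
    }
    paste(parts, collapse = "")
  }
  out <- render(0L)
  parse_smarts(out)  # must not fail on anything the translator emits
  out
}

# --- whole transforms --------------------------------------------------

#' @export
print.ss_reaction_rule <- function(x, ...) {
  cat(sprintf("<rule %d%s '%s': %s >> %s>\n", x$transform_id,
              if (nzchar(x$variant_tag)) paste0("/", x$variant_tag) else "",
              x$name, paste(x$reactant_smarts, collapse = " . "),
              x$product_smarts))
  invisible(x)
}

#' Translate a transform file to reaction rules
#'
#' A transform file holds `ID`, `NAME`, then one or more alternatives
#' (separated by `ALT`), each with 1-2 `REACTANT` pattern lines and one
#' `PRODUCT` pattern line. Product atom maps are implicit by node order
#' starting at one; reactant maps come from circumflex labels and must
#' cover all product maps. One rule is produced per pattern alternative
#' per fusion variant. Registered adjustments (declarative per-transform
#' SMARTS patches) are applied last.
#'
#' @param transform_text transform file contents as a single string or
#'   character vector of lines.
#' @param map translation map.
#' @param adjustments named list keyed by transform id; each entry a list
#'   of patches `list(side = 1|2|"product", from = , to = )` applied as
#'   literal replacements to the emitted SMARTS.
#' @param grammar grammar table.
#' @return List of `ss_reaction_rule` objects.
#' @export
translate_transform <- function(transform_text, map = translation_map(),
                                adjustments = list(),
                                grammar = patran_grammar()) {
  lines <- if (length(transform_text) == 1L)
    strsplit(transform_text, "\n", fixed = TRUE)[[1]] else transform_text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  id <- NA_integer_; name <- ""
  alts <- list(); current <- list(reactants = character(), product = NULL)
  flush_alt <- function() {
    if (length(current$reactants)) alts[[length(alts) + 1L]] <<- current
    current <<- list(reactants = character(), product = NULL)
  }
  for (ln in lines) {
    if (grepl("^ID\\s", ln)) id <- as.integer(sub("^ID\\s+", "", ln))
    else if (grepl("^NAME\\s", ln)) name <- sub("^NAME\\s+", "", ln)
    else if (grepl("^REACTANT\\s", ln))
      current$reactants <- c(current$reactants, sub("^REACTANT\\s+", "", ln))
    else if (grepl("^PRODUCT\\s", ln))
      current$product <- sub("^PRODUCT\\s+", "", ln)
    else if (ln == "ALT") flush_alt()
    else stop("unrecognized transform line: ", ln)
  }
  flush_alt()
  if (is.na(id)) stop("transform has no ID line")
  if (!length(alts)) stop("transform ", id, " has no pattern alternatives")
  rules <- list()
  for (a_i in seq_along(alts)) {
    alt <- alts[[a_i]]
    if (length(alt$reactants) > 2L)
      stop("transform ", id, ": more than two reactant patterns")
    if (is.null(alt$product)) stop("transform ", id, ": missing PRODUCT")
    rgraphs <- lapply(alt$reactants, parse_pattern, grammar = grammar)
    pgraph <- parse_pattern(alt$product, grammar = grammar)
    n_core <- length(pgraph$nodes)
    # validate maps
    side_of_map <- integer()
    for (s in seq_along(rgraphs)) {
      for (nd in rgraphs[[s]]$nodes) {
        if (!is.na(nd$map_number)) {
          if (nd$map_number %in% names2int(side_of_map))
            stop("transform ", id, ": duplicate atom map ", nd$map_number)
          side_of_map[as.character(nd$map_number)] <- s
        }
      }
    }
    missing <- setdiff(seq_len(n_core), names2int(side_of_map))
    if (length(missing))
      stop("transform ", id, ": product atoms ", paste(missing, collapse = ","),
           " have no mapped reactant atom")
    variant_sets <- lapply(rgraphs, expand_fusion_variants, map = map)
    combos <- expand.grid(lapply(variant_sets, seq_along))
    for (ci in seq_len(nrow(combos))) {
      vg <- lapply(seq_along(variant_sets), function(s)
        variant_sets[[s]][[combos[ci, s]]])
      tags <- vapply(vg, function(g) attr(g, "variant_tag"), "")
      tag <- paste(tags[nzchar(tags)], collapse = "+")
      if (length(alts) > 1L)
        tag <- paste0("alt", a_i, if (nzchar(tag)) paste0(".", tag) else "")
      r_smarts <- vapply(vg, emit_smarts, "", map = map, grammar = grammar,
                         side = "reactant")
      p_smarts <- emit_smarts(pgraph, map, grammar, side = "product")
      for (adj in adjustments[[as.character(id)]]) {
        if (identical(adj$side, "product")) {
          p_smarts <- gsub(adj$from, adj$to, p_smarts, fixed = TRUE)
        } else {
          s <- as.integer(adj$side)
          if (s <= length(r_smarts))
            r_smarts[s] <- gsub(adj$from, adj$to, r_smarts[s], fixed = TRUE)
        }
      }
      rule <- structure(list(
        transform_id = id, name = name,
        reactant_smarts = r_smarts, product_smarts = p_smarts,
        variant_tag = tag,
        link_mass_delta = rule_mass_delta(vg, pgraph, grammar, n_core),
        reactant_graphs = vg, product_graph = pgraph,
        reactant_patterns = lapply(r_smarts, parse_smarts),
        product_pattern = parse_smarts(p_smarts),
        n_core = n_core,
        side_of_map = side_of_map
      ), class = "ss_reaction_rule")
      rules[[length(rules) + 1L]] <- rule
    }
  }
  rules
}

names2int <- function(x) as.integer(names(x))

# Nominal mass change from reactants to product, computed from the
# patterns alone: leaving atoms (unmapped or mapped beyond the product)
# contribute their element mass plus pinned hydrogens; mapped atoms lose
# or gain hydrogens per the bond-order balance between pattern sides.
# NA when a leaving atom's hydrogen count is not pinned (halogens count
# as zero-H).
rule_mass_delta <- function(rgraphs, pgraph, grammar, n_core) {
  h_mass <- element_mass("H")
  total <- 0
  # product-side bond sums per map number
  prod_bond_sum <- numeric(n_core)
  for (e in pgraph$edges) {
    o <- bond_text_order(e$bond_text)
    prod_bond_sum[e$start + 1L] <- prod_bond_sum[e$start + 1L] + o
    prod_bond_sum[e$end + 1L] <- prod_bond_sum[e$end + 1L] + o
  }
  for (g in rgraphs) {
    react_bond_sum <- numeric(length(g$nodes))
    for (e in g$edges) {
      o <- bond_text_order(e$bond_text)
      react_bond_sum[e$start + 1L] <- react_bond_sum[e$start + 1L] + o
      react_bond_sum[e$end + 1L] <- react_bond_sum[e$end + 1L] + o
    }
    for (nd in g$nodes) {
      m <- nd$map_number
      leaving <- is.na(m) || m > n_core
      el <- grammar$atoms[[nd$atom_text]]
      if (leaving) {
        if (is.null(el) || el == "*") return(NA_real_)
        pinned <- NA_integer_
        for (p in nd$properties)
          if (p$keyword == "HS" && p$op == "=" && !p$negated)
            pinned <- as.integer(p$args[1])
        if (is.na(pinned)) {
          if (el %in% c("F", "Cl", "Br", "I")) pinned <- 0L
          else return(NA_real_)
        }
        total <- total + element_mass(el) + pinned * h_mass
      } else {
        h_loss <- prod_bond_sum[m] - react_bond_sum[nd$index + 1L]
        total <- total + h_loss * h_mass
      }
    }
  }
  -total
}
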