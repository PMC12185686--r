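# PATRAN-dialect tokenizer and pattern-graph builder. The concrete token
# syntax is loaded from a grammar data file so corrections to the dialect
# never touch code (see inst/extdata/patran_grammar.json).

.grammar_cache <- new.env(parent = emptyenv())

#' Load the PATRAN grammar table
#'
#' @param path optional path to a grammar JSON; defaults to the bundled
#'   grammar.
#' @return The grammar as a list (atom name map, bond map, property
#'   keyword lists, range enumeration cap).
#' @export
patran_grammar <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.grammar_cache$g)) return(.grammar_cache$g)
    path <- system.file("extdata", "patran_grammar.json",
                        package = "synthonspace", mustWork = FALSE)
    if (!nzchar(path) || !file.exists(path))
      path <- file.path("inst", "extdata", "patran_grammar.json")
    g <- jsonlite::read_json(path, simplifyVector = TRUE)
    .grammar_cache$g <- g
    return(g)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Tokenize a PATRAN-style pattern side
#'
#' Splits one pattern side into classified components: `ATOM`, `PROPERTY`,
#' `BOND`, `FUSION`, `START_SIDECHAIN`, `END_SIDECHAIN` and `RING`.
#' Concatenating the component texts in order reproduces the
#' whitespace-normalized input.
#'
#' @param pattern a single pattern side as text.
#' @param grammar grammar table from [patran_grammar()].
#' @return Data frame with columns `kind`, `text`, `position` (1-based
#'   character offset into the whitespace-stripped pattern).
#' @export
#' @examples
#' tokenize_pattern("N^1{HS>0}-C^2(=O)")
tokenize_pattern <- function(pattern, grammar = patran_grammar()) {
  s <- trimws(pattern)
  atom_names <- names(grammar$atoms)
  atom_names <- atom_names[order(nchar(atom_names), decreasing = TRUE)]
  atom_rx <- paste0("^(", paste(atom_names, collapse = "|"),
                    ")(\\^[0-9]+)?")
  bond_chars <- names(grammar$bonds)
  bond_rx <- paste0("^[", paste(c(setdiff(bond_chars, "-"),
                                  if ("-" %in% bond_chars) "-"),
                                collapse = ""), "]")
  kinds <- character(); texts <- character(); positions <- integer()
  pos <- 1L; n <- nchar(s)
  push <- function(kind, text) {
    kinds <<- c(kinds, kind); texts <<- c(texts, text)
    positions <<- c(positions, pos)
    pos <<- pos + nchar(text)
  }
  while (pos <= n) {
    rest <- substr(s, pos, n)
    ch <- substr(rest, 1, 1)
    if (grepl("^[[:space:]]$", ch)) { pos <- pos + 1L; next }
    if (ch == "(") { push("START_SIDECHAIN", "(") ; next }
    if (ch == ")") { push("END_SIDECHAIN", ")") ; next }
    m <- regmatches(rest, regexpr("^%[0-9]", rest))
    if (length(m)) { push("RING", m); next }
    m <- regmatches(rest, regexpr("^&!?[A-Z]+", rest))
    if (length(m)) {
      word <- sub("^&!?", "", m)
      if (word == "FUSION") push("FUSION", m)
      else if (word %in% grammar$bond_properties) push("PROPERTY", m)
      else stop("unknown bond property '", m, "' at position ", pos,
                " in pattern: ", pattern)
      next
    }
    m <- regmatches(rest, regexpr("^\\{[^}]*\\}", rest))
    if (length(m)) { push("PROPERTY", m); next }
    m <- regmatches(rest, regexpr(bond_rx, rest))
    if (length(m)) { push("BOND", m); next }
    m <- regmatches(rest, regexpr(atom_rx, rest))
    if (length(m)) { push("ATOM", m); next }
    stop("unknown token at position ", pos, " in pattern: ", pattern)
  }
  data.frame(kind = kinds, text = texts, position = positions)
}

parse_atom_property <- function(text) {
  body <- sub("^\\{", "", sub("\\}$", "", text))
  neg <- startsWith(body, "!")
  if (neg) body <- substring(body, 2L)
  m <- regmatches(body, regexpr("^[A-Z]+", body))
  if (!length(m)) stop("bad property text: ", text)
  keyword <- m
  rest <- substring(body, nchar(m) + 1L)
  op <- "="; args <- character()
  if (nzchar(rest)) {
    op <- substr(rest, 1, 1)
    if (!(op %in% c("=", ">", "<")))
      stop("bad property operator in: ", text)
    args <- strsplit(substring(rest, 2L), ",", fixed = TRUE)[[1]]
  }
  list(keyword = keyword, negated = neg, op = op, args = args)
}

#' Build a pattern graph from a component list
#'
#' Nodes appear in source order; properties attach to the preceding atom
#' (or preceding bond for `&`-style bond properties); side-chain markers
#' raise/lower the branch level; `%d` ring closures become edges whose
#' start node index exceeds the end node index, while sequential bonds
#' have start < end (all indices 0-based).
#'
#' @param components data frame from [tokenize_pattern()].
#' @param grammar grammar table.
#' @return An object of class `ss_pattern_graph` with `nodes` (list) and
#'   `edges` (list).
#' @export
build_pattern_graph <- function(components, grammar = patran_grammar()) {
  nodes <- list(); edges <- list()
  level <- 0L
  last_atom <- -1L          # 0-based index of previous chain atom
  branch_stack <- integer()
  pending_bond <- NULL      # list(text, properties)
  last_edge <- 0L           # 1-based index into edges of last completed edge
  ring_open <- list()
  for (r in seq_len(nrow(components))) {
    kind <- components$kind[r]; text <- components$text[r]
    if (kind == "ATOM") {
      map_number <- NA_integer_
      atom_text <- text
      if (grepl("\\^", text)) {
        parts <- strsplit(text, "^", fixed = TRUE)[[1]]
        atom_text <- parts[1]
        map_number <- as.integer(parts[2])
      }
      idx <- length(nodes)  # 0-based
      nodes[[idx + 1L]] <- list(index = idx, atom_text = atom_text,
                                properties = list(),
                                branch_level = level,
                                map_number = map_number)
      if (last_atom >= 0L) {
        bond <- if (is.null(pending_bond)) list(text = "-", properties = character())
                else pending_bond
        edges[[length(edges) + 1L]] <- list(start = last_atom, end = idx,
                                            bond_text = bond$text,
                                            properties = bond$properties)
        last_edge <- length(edges)
      }
      pending_bond <- NULL
      last_atom <- idx
    } else if (kind == "BOND") {
      pending_bond <- list(text = text, properties = character())
    } else if (kind == "FUSION" || (kind == "PROPERTY" && startsWith(text, "&"))) {
      prop <- sub("^&", "", text)
      if (!is.null(pending_bond)) {
        pending_bond$properties <- c(pending_bond$properties, prop)
      } else if (last_edge > 0L) {
        edges[[last_edge]]$properties <- c(edges[[last_edge]]$properties, prop)
      } else stop("bond property '", text, "' with no bond to attach to")
    } else if (kind == "PROPERTY") {
      if (last_atom < 0L)
        stop("property '", text, "' appears before any atom")
      p <- parse_atom_property(text)
      if (!(p$keyword %in% grammar$atom_properties))
        stop("unknown atom property keyword '", p$keyword, "'")
      nd <- nodes[[last_atom + 1L]]
      nd$properties <- c(nd$properties, list(p))
      nodes[[last_atom + 1L]] <- nd
    } else if (kind == "START_SIDECHAIN") {
      branch_stack <- c(branch_stack, last_atom)
      level <- level + 1L
    } else if (kind == "END_SIDECHAIN") {
      if (!length(branch_stack)) stop("unbalanced ')' in pattern")
      last_atom <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      level <- level - 1L
      pending_bond <- NULL
    } else if (kind == "RING") {
      key <- text
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        bond <- if (is.null(pending_bond)) list(text = "-", properties = character())
                else pending_bond
        # ring closure: start node succeeds end node
        edges[[length(edges) + 1L]] <- list(start = last_atom, end = op$atom,
                                            bond_text = bond$text,
                                            properties = bond$properties)
        last_edge <- length(edges)
        ring_open[[key]] <- NULL
        pending_bond <- NULL
      } else {
        if (last_atom < 0L) stop("ring closure before any atom")
        ring_open[[key]] <- list(atom = last_atom)
      }
    }
  }
  if (length(branch_stack)) stop("unbalanced '(' in pattern")
  open <- names(ring_open)[!vapply(ring_open, is.null, TRUE)]
  if (length(open))
    stop("ring closure ", paste(open, collapse = ","), " never closed")
  structure(list(nodes = nodes, edges = edges), class = "ss_pattern_graph")
}

#' @export
print.ss_pattern_graph <- function(x, ...) {
  cat(sprintf("<pattern graph: %d nodes, %d edges>\n",
              length(x$nodes), length(x$edges)))
  invisible(x)
}

#' Parse a PATRAN-style pattern side to a graph
#'
#' Convenience wrapper: [tokenize_pattern()] then [build_pattern_graph()].
#'
#' @inheritParams tokenize_pattern
#' @return An `ss_pattern_graph`.
#' @export
parse_pattern <- function(pattern, grammar = patran_grammar()) {
  build_pattern_graph(tokenize_pattern(pattern, grammar), grammar)
}
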