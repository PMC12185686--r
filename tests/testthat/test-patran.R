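# Tokenizer and pattern-graph construction.

test_that("tokenization classifies every segment and preserves the text", {
  toks <- tokenize_pattern("N")
  expect_equal(toks$kind, "ATOM")
  toks <- tokenize_pattern("C^1{HS=2}")
  expect_equal(toks$kind, c("ATOM", "PROPERTY"))
  expect_equal(toks$text, c("C^1", "{HS=2}"))
  toks <- tokenize_pattern("C-N")
  expect_equal(toks$kind, c("ATOM", "BOND", "ATOM"))
  expect_equal(toks$text[2], "-")
  # concatenation reproduces the (whitespace-normalized) input
  src <- "N^1{HS>0}-C^2(=O^3)-O{HS=1}"
  toks <- tokenize_pattern(src)
  expect_equal(paste(toks$text, collapse = ""), src)
  expect_true(all(diff(toks$position) > 0))
  # fusion and ring-bond annotations are their own component kinds
  toks <- tokenize_pattern("C:&!FUSION C")
  expect_true("FUSION" %in% toks$kind)
  toks <- tokenize_pattern("C-&RINGBOND C")
  expect_equal(toks$kind, c("ATOM", "BOND", "PROPERTY", "ATOM"))
  expect_error(tokenize_pattern("C?N"), "unknown token")
})

test_that("graphs keep source order, branch levels and edge orientation", {
  g <- parse_pattern("C-N")
  expect_length(g$nodes, 2L)
  expect_length(g$edges, 1L)
  expect_lt(g$edges[[1]]$start, g$edges[[1]]$end)
  # ring closure from atom 3 back to atom 1: stored with start > end
  g <- parse_pattern("C%1-C-C%1")
  expect_length(g$nodes, 3L)
  expect_length(g$edges, 3L)
  ring_edges <- Filter(function(e) e$start > e$end, g$edges)
  expect_length(ring_edges, 1L)
  expect_equal(ring_edges[[1]]$start, 2L)
  expect_equal(ring_edges[[1]]$end, 0L)
  # branch levels: zero is the main chain
  g <- parse_pattern("C(-N)-O")
  expect_equal(vapply(g$nodes, `[[`, 0L, "branch_level"), c(0L, 1L, 0L))
  # properties attach to the preceding atom
  g <- parse_pattern("N^1{HS=2}-C{FGS=CARBOXYL}")
  expect_equal(g$nodes[[1]]$map_number, 1L)
  expect_equal(g$nodes[[1]]$properties[[1]]$keyword, "HS")
  expect_equal(g$nodes[[2]]$properties[[1]]$args, "CARBOXYL")
})

test_that("malformed patterns fail with position information", {
  expect_error(build_pattern_graph(tokenize_pattern("{HS=2}C")),
               "before any atom")
  expect_error(parse_pattern("C(-N"), "unbalanced")
  expect_error(parse_pattern("C%1-C"), "never closed")
})

test_that("round trip: one node per ATOM, one edge per bond or closure", {
  set.seed(7)
  atoms <- c("C", "N", "O", "S")
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    parts <- sample(atoms, n, replace = TRUE)
    # random linear chain with an optional branch and optional ring
    txt <- parts[1]
    branch_at <- if (n >= 4 && runif(1) < 0.5) sample(2:(n - 2), 1) else 0L
    for (i in 2:n) {
      piece <- paste0("-", parts[i])
      txt <- if (i == branch_at) paste0(txt, "(", piece, ")") else
        paste0(txt, piece)
    }
    close_ring <- n >= 4 && branch_at == 0L && runif(1) < 0.5
    if (close_ring) {
      txt <- sub("^([A-Z][a-z]?)", "\\1%1", txt)
      txt <- paste0(txt, "%1")
    }
    toks <- tokenize_pattern(txt)
    g <- build_pattern_graph(toks)
    expect_length(g$nodes, sum(toks$kind == "ATOM"))
    expect_length(g$edges,
                  sum(toks$kind == "BOND") + close_ring * 0L +
                    (sum(toks$kind == "RING") / 2))
    # orientation invariant
    for (e in g$edges) expect_true(e$start != e$end)
    seq_edges <- Filter(function(e) e$start < e$end, g$edges)
    expect_length(seq_edges, sum(toks$kind == "BOND"))
    # branch-level oracle: parenthesis depth at each atom in the source
    depth <- 0L; lev <- integer()
    for (ch in strsplit(gsub("%1|\\^[0-9]+", "", txt), "")[[1]]) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (grepl("[A-Z]", ch)) lev <- c(lev, depth)
    }
    expect_equal(vapply(g$nodes, `[[`, 0L, "branch_level"), lev,
                 label = txt)
  }
})
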