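# Synthons, counting, enumeration, retro-validation, membership,
# histograms, serialization.

small_world <- function(amines, acids) {
  bbs <- c(lapply(seq_along(amines), function(i)
    pmol_id(amines[i], sprintf("am%02d", i))),
    lapply(seq_along(acids), function(i)
      pmol_id(acids[i], sprintf("ac%02d", i))))
  rules <- toy_rules("amide")
  srs <- filter_building_blocks(rules, bbs, policy = "SPACE",
                                rulesets = toy_ruleset("amide"))
  build_space(srs, "small", model = "DEFAULT")
}

test_that("counting is the sub-reaction pair sum, with exact arithmetic", {
  sp <- small_world(c("NCC", "NCCC", "NCCCC"),
                    c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "OC(=O)c1ccccc1"))
  expect_equal(count_products(sp), 12)
  expect_equal(nrow(enumerate_products(sp, Inf, 1)), 12L)
  # empty side: zero products (symmetric alkene pattern under SPACE)
  expect_equal(count_products(toy_space("alkene_symmetric")), 0)
  # overflow guard
  fake <- structure(list(graphs = list(list(side1 = vector("list", 2),
                                            side2 = vector("list", 2)))),
                    class = "ss_fragment_space")
  expect_equal(count_products(fake), 4)
})

test_that("synthons carry typed links and conserve mass", {
  sp <- small_world("NCC", "CC(=O)O")
  g <- sp$graphs[[1]]
  syn1 <- g$side1[[1]]; syn2 <- g$side2[[1]]
  expect_equal(sum(syn1$fragment$atoms$element == "*"), 1L)
  expect_equal(sum(syn2$fragment$atoms$element == "*"), 1L)
  # water loss: fragments sum to reactants minus 18.015 g/mol
  delta <- (syn1$mass_contribution + syn2$mass_contribution) -
    (mol_mw(parse_smiles("NCC")) + mol_mw(parse_smiles("CC(=O)O")))
  expect_equal(delta, -18.015, tolerance = 1e-3)
  # and the assembled product weighs exactly the synthon sum
  enum <- enumerate_products(sp, Inf, 1)
  expect_equal(mol_mw(parse_smiles(enum$smiles[1])),
               syn1$mass_contribution + syn2$mass_contribution,
               tolerance = 1e-9)
})

test_that("protected reactants are stored as deprotected synthons", {
  boc <- pmol_id("CC(C)(C)OC(=O)NCCC(=S)N", "boc_thioamide")
  bbs <- c(list(boc), list(pmol_id("BrCC(=O)C", "ket")))
  srs <- filter_building_blocks(toy_rules("thiazole"), bbs,
                                policy = "SPACE",
                                rulesets = toy_ruleset("thiazole"))
  sp <- build_space(srs, "dp", model = "DEFAULT")
  keys <- unlist(lapply(sp$graphs, function(g)
    vapply(g$side1, `[[`, "", "key")))
  expect_length(keys, 1L)
  expect_false(grepl("C\\(C\\)\\(C\\)", keys))  # no tert-butyl left
  # free primary amine present on the stored fragment
  frag <- sp$graphs[[1]]$side1[[1]]$fragment
  expect_true(smarts_has_match(frag, "[NX3;H2]"))
})

test_that("reactants implying non-favored valence states are dropped", {
  # a transform forming two bonds at the amine nitrogen: a secondary
  # amine would need N(IV) uncharged and is dropped at synthon build
  txt <- paste("ID 9200", "NAME double N-alkylation",
               "REACTANT N^1{HS>0}",
               "REACTANT O{HS=1}-C^2{HS=2}-C^3{HS=3}",
               "PRODUCT N%1-C-C%1", sep = "\n")
  rules <- translate_transform(txt)
  bbs <- list(pmol_id("NCC", "prim"), pmol_id("CNC", "sec"),
              pmol_id("OCC", "eth"))
  srs <- filter_building_blocks(rules, bbs, policy = "SPACE")
  sp <- build_space(srs, "valence", model = "DEFAULT")
  ids <- unlist(lapply(sp$graphs, function(g)
    vapply(g$side1, function(s) s$provenance$bb_id, "")))
  expect_true("prim" %in% ids)
  expect_false("sec" %in% ids)
  expect_true("sec" %in% sp$dropped$bb_id)
  expect_match(sp$dropped$reason[sp$dropped$bb_id == "sec"], "valence|hydrogen")
})

test_that("enumeration is seeded, uniform and assembly-checked", {
  sp <- toy_space("amide")
  full <- enumerate_products(sp, Inf, 1)
  expect_equal(nrow(full), count_products(sp))
  e1 <- enumerate_products(sp, 15, 7)
  e2 <- enumerate_products(sp, 15, 7)
  e3 <- enumerate_products(sp, 15, 8)
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
  expect_equal(nrow(e1), 15L)
  # every product of the amide space contains the amide bond
  for (s in full$smiles) {
    expect_true(smarts_has_match(pmol(s), "[NX3][CX3]=[OX1]"), label = s)
  }
})

test_that("retro-validation accepts own products and rejects impostors", {
  sp <- toy_space("thiazole")
  enum <- toy_enumeration("thiazole")
  ok <- vapply(seq_len(nrow(enum)), function(i)
    retro_validate(enum$smiles[i], sp, enum$graph[i],
                   enum$bb1[i], enum$bb2[i]), TRUE)
  expect_true(all(ok))
  # hand-edited product: swapped ring substitution pattern
  # (regiochemistry mismatch must fail the product pattern + cut check)
  good <- enum$smiles[1]
  expect_false(retro_validate("CCCCCC", sp, enum$graph[1],
                              enum$bb1[1], enum$bb2[1]))
  # wrong provenance fails even for a genuine product
  expect_false(retro_validate(good, sp, enum$graph[1], "nope", "nada"))
})

test_that("regiochemistry encoded in the product pattern is enforced", {
  # thiazole from thiopropionamide + bromoacetone: substituents sit on
  # ring positions 2 and 4; the 2,5-regioisomer is not in the space
  bbs <- list(pmol_id("NC(=S)CC", "thio"), pmol_id("BrCC(=O)C", "ket"))
  srs <- filter_building_blocks(toy_rules("thiazole"), bbs, policy = "SPACE",
                                rulesets = toy_ruleset("thiazole"))
  sp <- build_space(srs, "regio", model = "DEFAULT")
  enum <- enumerate_products(sp, Inf, 1)
  expect_equal(nrow(enum), 1L)
  # 2-ethyl-4-methylthiazole is the true product; the 2,5-isomer is not
  regio_wrong <- "CCc1sc(C)cn1"
  expect_false(canonical_smiles(regio_wrong, "DEFAULT") ==
                 canonical_smiles(enum$smiles[1], "DEFAULT"))
  expect_length(space_contains(sp, regio_wrong), 0L)
  expect_true(length(space_contains(sp, enum$smiles[1])) > 0L)
})

test_that("membership lookup is exact and reports every route", {
  sp <- toy_space("amide")
  enum <- toy_enumeration("amide")
  # no false negatives, provenance round-trips
  for (i in seq_len(nrow(enum))) {
    hits <- space_contains(sp, enum$smiles[i])
    expect_true(any(vapply(hits, function(h)
      h$bb1 == enum$bb1[i] && h$bb2 == enum$bb2[i], TRUE)),
      label = enum$smiles[i])
  }
  # no false positives
  expect_length(space_contains(sp, "CCCCCCCC"), 0L)
  expect_length(space_contains(sp, "c1ccccc1"), 0L)
  # a deliberate overlap: two transforms with identical chemistry; every
  # product is constructible through both
  rules <- c(toy_rules("amide"), toy_rules("amide_goto"))
  rulesets <- c(toy_ruleset("amide"), toy_ruleset("amide_goto"))
  srs <- filter_building_blocks(rules,
                                list(pmol_id("NCc1ccccc1", "am"),
                                     pmol_id("CCC(=O)O", "ac")),
                                policy = "SPACE", rulesets = rulesets)
  sp2 <- build_space(srs, "overlap", model = "DEFAULT")
  prod <- enumerate_products(sp2, Inf, 1)
  hits <- space_contains(sp2, prod$smiles[1])
  expect_length(hits, 2L)
  expect_setequal(vapply(hits, `[[`, 0L, "transform_id"), c(9001L, 9005L))
})

test_that("histogram convolution is bin-exact against enumeration", {
  sp <- toy_space("amide")
  enum <- toy_enumeration("amide")
  h <- property_histograms(sp, "MW")
  expect_equal(sum(h$counts), count_products(sp))
  emw <- vapply(enum$smiles, function(s) mol_mw(parse_smiles(s)), 0)
  ref <- hist(emw, breaks = h$breaks, plot = FALSE)$counts
  expect_equal(h$counts, as.numeric(ref))
  # single-pair space: one occupied bin with count one
  sp1 <- small_world("NCC", "CC(=O)O")
  h1 <- property_histograms(sp1, "MW")
  expect_equal(sum(h1$counts), 1)
  expect_equal(sum(h1$counts > 0), 1L)
  # non-additive request errors
  expect_error(property_histograms(toy_space("thiazole"), "ROTB"),
               "not additive")
  expect_error(property_histograms(sp, "clogP"), "unsupported")
})

test_that("serialization round-trips counts, histograms and membership", {
  sp <- toy_space("thiazole")
  dir <- tempfile("space")
  serialize_space(sp, dir)
  sp2 <- load_space(dir)
  expect_equal(count_products(sp2), count_products(sp))
  expect_equal(property_histograms(sp2, "MW")$counts,
               property_histograms(sp, "MW")$counts)
  q <- toy_enumeration("thiazole")$smiles[1]
  expect_equal(length(space_contains(sp2, q)), length(space_contains(sp, q)))
  # tampering is detected
  unlink(file.path(dir, "graph001_side1.smi"))
  expect_error(load_space(dir), "missing synthon file")
  expect_error(load_space(tempfile()), "manifest")
})

test_that("coverage estimates are exact on constructed overlaps", {
  acids <- c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "OC(=O)c1ccccc1")
  big <- small_world(c("NCC", "NCCC"), acids)
  small <- small_world(c("NCC", "NCCC"), acids[1:2])
  cov_self <- coverage_estimate(big, big, per_transform_n = 100, seed = 1)
  expect_equal(cov_self$fraction, 1)
  cov_ab <- coverage_estimate(small, big, per_transform_n = 100, seed = 1)
  expect_equal(cov_ab$fraction, 1)
  cov_ba <- coverage_estimate(big, small, per_transform_n = 100, seed = 1)
  expect_equal(cov_ba$fraction, count_products(small) / count_products(big))
  disjoint <- coverage_estimate(big, toy_space("thiazole"),
                                per_transform_n = 20, seed = 1)
  expect_equal(disjoint$fraction, 0)
})
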