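# Building-block selection policies, masking, and sub-reaction splitting.

test_that("duplicate policies differ exactly as specified", {
  rule <- toy_rules("chanlam")[[1]]
  sec <- pmol_id("CCNCC", "sec_amine")
  # secondary amine: two embeddings that differ only in the spectator
  # carbon -> same product; SPACE keeps it, LIB2020 drops it
  m_space <- match_building_blocks(rule, list(sec), "SPACE")
  expect_length(m_space$records, 1L)
  m_lib <- match_building_blocks(rule, list(sec), "LIB2020")
  expect_length(m_lib$records, 0L)
  expect_equal(m_lib$excluded$reason, "multi_match")
  # primary amine: single embedding under both policies
  prim <- pmol_id("CCN", "prim_amine")
  expect_length(match_building_blocks(rule, list(prim), "SPACE")$records, 1L)
  expect_length(match_building_blocks(rule, list(prim), "LIB2020")$records, 1L)
  # symmetric alkene pattern: double match is a product mixture under
  # SPACE, a same-atom unification under LIB2020
  arule <- toy_rules("alkene_symmetric")[[1]]
  alk <- pmol_id("CC=CC", "butene")
  expect_length(match_building_blocks(arule, list(alk), "SPACE")$records, 0L)
  expect_length(match_building_blocks(arule, list(alk), "LIB2020")$records, 1L)
  # neither side: reported as no_match
  m <- match_building_blocks(rule, list(pmol_id("CCCC", "alkane")), "SPACE")
  expect_equal(m$excluded$reason, "no_match")
})

test_that("both-side matchers are excluded unless one side is killed", {
  rule <- toy_rules("amide")[[1]]
  rs <- load_kill_ruleset(toy_transform_suite()$amide$kills)
  aa <- pmol_id("NCCC(=O)O", "amino_acid")
  m <- match_building_blocks(rule, list(aa), "SPACE", ruleset = rs)
  expect_equal(m$excluded$reason, "both_sides")
  # alpha-bromo amino acid: the acid-side match is killed (OFFPATH
  # halide), so the amine side is rescued
  ba <- pmol_id("NCC(Br)C(=O)O", "bromo_amino_acid")
  m <- match_building_blocks(rule, list(ba), "SPACE", ruleset = rs)
  expect_length(m$records, 1L)
  expect_equal(m$records[[1]]$pattern_side, 1L)
  # without the ruleset there is no rescue
  m <- match_building_blocks(rule, list(ba), "SPACE")
  expect_equal(m$excluded$reason, "both_sides")
})

test_that("masking replaces leaving groups and labels the backbone", {
  rule <- toy_rules("biaryl_fusion")[[1]]
  arbr <- pmol_id("Brc1ccccc1", "bromobenzene")
  rec <- match_building_blocks(rule, list(arbr), "SPACE")$records[[1]]
  mv <- prepare_masked_variants(rec, rule)
  va <- mv$variant_a
  # bromine gone, one mask dummy in its place
  expect_false("Br" %in% va$atoms$element)
  expect_equal(sum(va$atoms$element == "*"), 1L)
  # backbone labels: map numbers + 100 in the isotope slot
  expect_setequal(va$atoms$isotope[va$atoms$isotope > 0], c(101L, 102L))
  # masking conserves heavy atoms: input - leaving + masks
  expect_equal(synthonspace:::heavy_atom_count(va),
               synthonspace:::heavy_atom_count(arbr) -
                 length(mv$leaving_atoms) + 1L)
  # labels are identical across variants
  expect_identical(mv$variant_a$atoms$isotope[seq_len(n_atoms(mv$variant_a))],
                   mv$variant_b$atoms$isotope)
})

test_that("variant b cuts every bond of the mapped backbone", {
  rule <- toy_rules("thiazole")[[1]]
  th <- pmol_id("NC(=S)CC", "thioamide")
  rec <- match_building_blocks(rule, list(th), "SPACE")$records[[1]]
  mv <- prepare_masked_variants(rec, rule)
  lab <- unname(mv$labels)   # three mapped atoms: N, C, S
  expect_length(lab, 3L)
  b <- mv$variant_b$bonds
  expect_equal(sum(b$a1 %in% lab & b$a2 %in% lab), 0L)
  # variant a keeps them
  ba <- mv$variant_a$bonds
  expect_equal(sum(ba$a1 %in% lab & ba$a2 %in% lab), 2L)
})

test_that("reactants with all atoms mapped mask to the labelled input", {
  rule <- toy_rules("chanlam")[[1]]
  prim <- pmol_id("CCN", "prim")
  rec <- match_building_blocks(rule, list(prim), "SPACE")$records[[1]]
  mv <- prepare_masked_variants(rec, rule)
  expect_length(mv$leaving_atoms, 0L)
  expect_equal(sum(mv$variant_a$atoms$element == "*"), 0L)
  expect_equal(n_atoms(mv$variant_a), n_atoms(prim))
})

test_that("sub-reaction splitting matches the brute-force pair oracle", {
  # no cross-side statements: exactly one sub-reaction with all survivors
  sp <- toy_space("amide")
  expect_length(sp$graphs, 1L)
  # two cross-side statements (one with GOTO): several sub-reactions,
  # pair set identical to the product-level oracle, no pair duplicated
  spt <- toy_space("thiazole")
  expect_gte(length(spt$graphs), 2L)
  enum <- toy_enumeration("thiazole")
  orc <- toy_oracle("thiazole")
  expect_setequal(paste(enum$bb1, enum$bb2),
                  paste(orc$bb1[!orc$killed], orc$bb2[!orc$killed]))
  expect_equal(anyDuplicated(paste(enum$bb1, enum$bb2)), 0L)
})

test_that("fusion variants never hand one block to two sub-patterns", {
  sp <- toy_space("biaryl_fusion")
  seen <- character()
  for (g in sp$graphs) {
    for (s in g$side1) seen <- c(seen, s$provenance$bb_id)
  }
  expect_equal(anyDuplicated(seen), 0L)
  enum <- toy_enumeration("biaryl_fusion")
  expect_equal(anyDuplicated(paste(enum$bb1, enum$bb2)), 0L)
})

test_that("exclusions carry machine-readable reasons", {
  srs <- attr(toy_space("amide"), "subreactions")
  ex <- attr(srs, "exclusions")
  expect_true(all(c("bb_id", "transform_id", "reason") %in% names(ex)))
  expect_true(any(grepl("^killed:", ex$reason)))
  expect_true("no_match" %in% ex$reason)
  expect_true("both_sides" %in% ex$reason)
})
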