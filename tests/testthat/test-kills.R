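# KILL ruleset loading and the masked ONPATH/OFFPATH/GOTO evaluation.

test_that("ruleset loading validates schema, SMARTS and GOTO targets", {
  rs <- load_kill_ruleset(toy_transform_suite()$amide$kills)
  expect_s3_class(rs, "ss_kill_ruleset")
  expect_length(rs$statements, 3L)
  expect_equal(rs$statements[[2]]$scope, "OFFPATH")
  expect_equal(rs$statements[[2]]$participants, 2L)
  expect_equal(rs$untranslatable, "LESS*HINDERED")
  # dangling GOTO: target 5 with only statements 1..4
  bad <- list(transform = 1L, statements = list(
    list(index = 1L, smarts = list("[#6]"), scope = "ONPATH",
         participants = list(), goto = 5L),
    list(index = 2L, smarts = list("[#6]"), scope = "ONPATH",
         participants = list(), goto = NULL),
    list(index = 3L, smarts = list("[#6]"), scope = "ONPATH",
         participants = list(), goto = NULL),
    list(index = 4L, smarts = list("[#6]"), scope = "ONPATH",
         participants = list(), goto = NULL)), untranslatable = list())
  expect_error(load_kill_ruleset(bad), "GOTO target 5")
  bad$statements[[1]]$goto <- NULL
  bad$statements[[1]]$smarts <- list("[not a smarts")
  expect_error(load_kill_ruleset(bad))
  bad$statements[[1]]$smarts <- list("[#6]")
  bad$statements[[1]]$scope <- "SIDEWAYS"
  expect_error(load_kill_ruleset(bad), "scope")
})

test_that("an empty ruleset yields an empty signature and never kills", {
  rs <- load_kill_ruleset(list(transform = 1L, statements = list(),
                               untranslatable = list()))
  rule <- toy_rules("amide")[[1]]
  rec <- match_building_blocks(rule, list(
    pmol_id("NCCC", "a1")), "SPACE")$records[[1]]
  mv <- prepare_masked_variants(rec, rule)
  sig <- evaluate_kills(mv, rs, 1L, rule)
  expect_false(sig$killed)
  expect_equal(sig$paths, list(list()))
})

test_that("ONPATH sees the reaction path that OFFPATH must not", {
  rule <- toy_rules("amide")[[1]]
  # hetero alpha to the acid carbon (atom 2): the carbonyl oxygen IS such
  # a neighbour, but it lies on the reaction path
  onpath <- load_kill_ruleset(list(transform = 9001L, statements = list(
    list(index = 1L, smarts = list("[102*]~[!#6;!#1]"), scope = "ONPATH",
         participants = list(2L), goto = NULL)), untranslatable = list()))
  offpath <- load_kill_ruleset(list(transform = 9001L, statements = list(
    list(index = 1L, smarts = list("[102*]~[!#6;!#1]"), scope = "OFFPATH",
         participants = list(2L), goto = NULL)), untranslatable = list()))
  rec <- match_building_blocks(rule, list(pmol_id("CCC(=O)O", "acid")),
                               "SPACE")$records[[1]]
  mv <- prepare_masked_variants(rec, rule)
  expect_true(evaluate_kills(mv, onpath, 2L, rule)$killed)    # via C=O
  expect_false(evaluate_kills(mv, offpath, 2L, rule)$killed)  # path masked
  # an off-path heteroatom triggers both scopes
  rec2 <- match_building_blocks(rule, list(pmol_id("COC(=O)O", "carb")),
                                "SPACE")$records[[1]]
  mv2 <- prepare_masked_variants(rec2, rule)
  expect_true(evaluate_kills(mv2, offpath, 2L, rule)$killed)
})

test_that("OFFPATH alpha-halide statement kills only halogenated acids", {
  rule <- toy_rules("amide")[[1]]
  rs <- load_kill_ruleset(toy_transform_suite()$amide$kills)
  halo <- match_building_blocks(rule, list(pmol_id("OC(=O)CBr", "halo")),
                                "SPACE")$records[[1]]
  sig <- evaluate_kills(prepare_masked_variants(halo, rule), rs, 2L, rule)
  expect_true(sig$killed)
  plain <- match_building_blocks(rule, list(pmol_id("OC(=O)CC", "plain")),
                                 "SPACE")$records[[1]]
  sig <- evaluate_kills(prepare_masked_variants(plain, rule), rs, 2L, rule)
  expect_false(sig$killed)
  # untranslatable statement 3 is recorded as skipped, not triggered
  expect_true(3L %in% sig$skipped)
})

test_that("GOTO skips the kill for reactants that trigger it", {
  rule <- toy_rules("amide_goto")[[1]]
  rs <- load_kill_ruleset(toy_transform_suite()$amide_goto$kills)
  trace <- function(smi) {
    rec <- match_building_blocks(rule, list(pmol_id(smi, "x")),
                                 "SPACE")$records[[1]]
    evaluate_kills(prepare_masked_variants(rec, rule), rs, 1L, rule)
  }
  expect_false(trace("NCc1ccccc1")$killed)  # benzylic: GOTO 3 rescues
  expect_true(trace("NCCC")$killed)         # no trigger: statement 2 kills
  expect_false(trace("Nc1ccccc1")$killed)   # aniline: neither fires
})

test_that("anywhere statements branch on the partner reactant", {
  rule <- toy_rules("amide")[[1]]
  rs <- load_kill_ruleset(toy_transform_suite()$amide$kills)
  rec <- match_building_blocks(rule, list(pmol_id("OC(=O)CC", "acid")),
                               "SPACE")$records[[1]]
  sig <- evaluate_kills(prepare_masked_variants(rec, rule), rs, 2L, rule)
  # statement 1 (nitro anywhere) is undecidable from the acid alone:
  # both branches appear in the nested path list
  trig1 <- vapply(sig$paths, function(p) p[[1]]$triggered, TRUE)
  expect_setequal(trig1, c(TRUE, FALSE))
})

test_that("same-ring constraints enumerate ring-bond distances", {
  alts <- kill_same_ring_smarts("[#7;R]", "[#8;R]", 6)
  expect_length(alts, 6L)
  for (a in alts) expect_s3_class(parse_smarts(a), "ss_smarts")
  morpholine <- pmol("C1COCCN1")
  hit <- any(vapply(alts, function(a)
    smarts_has_match(morpholine, a), TRUE))
  expect_true(hit)
  # distances beyond the molecule's ring are not reachable
  short <- kill_same_ring_smarts("[#7;R]", "[#8;R]", 1)
  expect_false(smarts_has_match(morpholine, short[1]))
})
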