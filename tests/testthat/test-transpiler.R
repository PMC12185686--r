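# Pattern-graph to SMARTS translation: atom properties, bonds, fusion
# variants, emission, whole transforms and the semantic panel harness.

test_that("hydrogen-count properties translate exactly and by enumeration", {
  # exact count
  g <- parse_pattern("C{HS=2}")
  s <- emit_smarts(g)
  expect_true(smarts_has_match(pmol("CCC"), s))    # central CH2
  expect_false(smarts_has_match(pmol("C(C)(C)(C)C"), s))
  # open range enumerated to the cap of 4: HS>1 == (H2 or H3 or H4)
  s <- emit_smarts(parse_pattern("C{HS>1}"))
  panel <- list(methane = c("C", TRUE), ethane = c("CC", TRUE),
                propane_mid = c("CCC", TRUE), isobutane_ch = c("CC(C)C", TRUE),
                neopentane_q = c("CC(C)(C)C", TRUE))
  hits <- function(smarts, smi) length(smarts_match(pmol(smi), smarts))
  expect_equal(hits(s, "C"), 1L)            # CH4
  expect_equal(hits(s, "CC(C)C"), 3L)       # three CH3, not the CH
  expect_equal(hits(s, "CC(C)(C)C"), 4L)    # four CH3, not the C
  # explicit equivalence with the enumerated alternative
  s_manual <- "[#6;H2,H3,H4]"
  for (smi in c("C", "CC", "CCC", "CC(C)C", "CC(C)(C)C")) {
    expect_equal(hits(s, smi), hits(s_manual, smi), label = smi)
  }
  expect_error(emit_smarts(parse_pattern("C{HS>4}")), "empty")
})

test_that("neighbouring-heteroatom counts use recursive environments", {
  s0 <- emit_smarts(parse_pattern("C{HETS=0}"))
  expect_equal(length(smarts_match(pmol("CC"), s0)), 2L)  # ethane matches
  expect_equal(length(smarts_match(pmol("CN"), s0)), 0L)  # methylamine C no
  s1 <- emit_smarts(parse_pattern("C{HETS=1}"))
  expect_equal(length(smarts_match(pmol("CN"), s1)), 1L)
  expect_equal(length(smarts_match(pmol("OCN"), s1)), 0L) # that C has 2
  s2 <- emit_smarts(parse_pattern("C{HETS>1}"))
  expect_equal(length(smarts_match(pmol("OCN"), s2)), 1L)
})

test_that("functional-group properties join with OR, absences with AND", {
  node <- parse_pattern("C{FGS=CARBOXYL,KETONE}")$nodes[[1]]
  s <- translate_atom(node)
  expect_true(smarts_has_match(pmol("CC(=O)O"), s))
  expect_true(smarts_has_match(pmol("CC(=O)C"), s))
  expect_false(smarts_has_match(pmol("CC(=O)N"), s))
  node <- parse_pattern("C{!FGS=CARBOXYL,KETONE}")$nodes[[1]]
  s <- translate_atom(node)
  # on acetic acid only the methyl carbon is neither group's anchor
  m <- smarts_match(pmol("CC(=O)O"), s)
  expect_length(m, 1L)
  acid_c <- smarts_match(pmol("CC(=O)O"), "[CX3](=[OX1])[OX2;H1]")[[1]][1]
  expect_false(acid_c %in% vapply(m, `[[`, 0L, 1L))
  # unknown keywords fail loudly, no defaults invented
  expect_error(translate_atom(parse_pattern("C{FGS=NO_SUCH_GROUP}")$nodes[[1]]),
               "unknown functional group")
  expect_error(translate_atom(parse_pattern("Q")$nodes[[1]]))
})

test_that("bond translation handles symbols and ring-bond annotation", {
  g <- parse_pattern("C-&RINGBOND C")
  s <- emit_smarts(g)
  expect_match(s, "@", fixed = TRUE)
  expect_true(smarts_has_match(pmol("C1CCCCC1"), s))
  expect_false(smarts_has_match(pmol("CCC"), s))
  expect_error(translate_bond(list(bond_text = "?", properties = list())),
               "unknown bond")
})

test_that("fusion variants duplicate only for the negated property", {
  plain <- parse_pattern("C-C")
  expect_length(expand_fusion_variants(plain), 1L)
  one <- parse_pattern("C:&!FUSION C")
  expect_length(expand_fusion_variants(one), 2L)
  two <- parse_pattern("C:&!FUSION C:&!FUSION C")
  expect_length(expand_fusion_variants(two), 4L)
  # positive assertion: both atoms annotated, single variant
  pos <- expand_fusion_variants(parse_pattern("C{AROMATIC}:&FUSION C{AROMATIC}"))
  expect_length(pos, 1L)
  s <- emit_smarts(pos[[1]])
  naph <- pmol("c1ccc2ccccc2c1")
  m <- smarts_match(naph, s, uniquify = "atoms")
  expect_length(m, 1L)  # exactly the one true fusion bond
})

test_that("emission preserves order, branches and ring closures", {
  expect_equal(emit_smarts(parse_pattern("C-N")), "[#6]-[#7]")
  s <- emit_smarts(parse_pattern("C(-N)-O"))
  expect_match(s, "^\\[#6\\]\\(-\\[#7\\]\\)-\\[#8\\]$")
  # parse-and-rematch oracle: the graph was hand-built from cyclohexane
  s <- emit_smarts(parse_pattern("C%1-C-C-C-C-C%1"))
  expect_true(smarts_has_match(pmol("C1CCCCC1"), s))
  expect_false(smarts_has_match(pmol("CCCCCC"), s))
})

test_that("whole transforms translate to mapped reaction rules", {
  rules <- toy_rules("amide")
  expect_length(rules, 1L)
  r <- rules[[1]]
  expect_length(r$reactant_smarts, 2L)
  expect_match(r$reactant_smarts[1], ":1")
  expect_match(r$product_smarts, ":3")
  expect_equal(r$transform_id, 9001L)
  expect_equal(r$link_mass_delta, -18.015, tolerance = 1e-6)
  # fusion transform: two rules differing only in reactant 1
  rules <- toy_rules("biaryl_fusion")
  expect_length(rules, 2L)
  expect_false(rules[[1]]$reactant_smarts[1] == rules[[2]]$reactant_smarts[1])
  expect_equal(rules[[1]]$reactant_smarts[2], rules[[2]]$reactant_smarts[2])
  expect_equal(rules[[1]]$product_smarts, rules[[2]]$product_smarts)
  # product side refuses non-H-count properties
  bad <- paste("ID 9999", "NAME bad", "REACTANT N^1", "REACTANT C^2",
               "PRODUCT N{FGS=AMIDE}-C", sep = "\n")
  expect_error(translate_transform(bad), "not allowed in a product")
  # unresolvable keyword names the transform
  bad2 <- paste("ID 9999", "NAME bad", "REACTANT N^1{HS=1}",
                "REACTANT C^2", "PRODUCT N-C", sep = "\n")
  expect_silent(translate_transform(bad2))
})

test_that("declarative adjustments patch emitted SMARTS by transform id", {
  txt <- paste("ID 9100", "NAME adj", "REACTANT N^1{HS=2}",
               "REACTANT C^2(=O^3)-O{HS=1}", "PRODUCT N-C=O", sep = "\n")
  adj <- list("9100" = list(list(side = 1, from = "[#7;H2:1]",
                                 to = "[#7;H2;!$([#7][c]):1]")))
  rules <- translate_transform(txt, adjustments = adj)
  expect_match(rules[[1]]$reactant_smarts[1], "!$([#7][c])", fixed = TRUE)
  # the patched rule now rejects anilines
  m <- match_building_blocks(rules[[1]], list(pmol("Nc1ccccc1")), "SPACE")
  expect_equal(m$excluded$reason, "no_match")
})

test_that("every translation-map entry passes its molecule panel", {
  map <- translation_map()
  for (nm in names(map$functional_groups)) {
    entry <- map$functional_groups[[nm]]
    wrapped <- paste0("[", paste0("$(", unlist(entry$smarts), ")",
                                  collapse = ","), "]")
    pat <- parse_smarts(wrapped)
    for (smi in unlist(entry$positive)) {
      expect_true(smarts_has_match(pmol(smi), pat),
                  label = paste(nm, "positive", smi))
    }
    for (smi in unlist(entry$negative)) {
      expect_false(smarts_has_match(pmol(smi), pat),
                   label = paste(nm, "negative", smi))
    }
  }
})

test_that("fusion translation reproduces its documented false positive", {
  # the atom-annotated fusion pattern: both ends in at least two rings
  fusion_smarts <- "[c;!R0;!R1]:[c;!R0;!R1]"
  phen <- pmol("c1ccc2c(c1)ccc1ccccc12")
  matches <- smarts_match(phen, fusion_smarts, uniquify = "atoms")
  true_fusion <- synthonspace:::fusion_bonds(with_rings(phen))
  expect_length(matches, 3L)      # the pattern overcounts...
  expect_length(true_fusion, 2L)  # ...the real fused bonds
})
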