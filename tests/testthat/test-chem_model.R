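# Standardization, aromaticity models, valence checking and
# protecting-group removal.

test_that("standardize applies the named cleanup rules", {
  # carboxylate protonation
  expect_equal(write_smiles(standardize(parse_smiles("CC(=O)[O-]"))),
               write_smiles(parse_smiles("CC(=O)O")))
  # salt stripping keeps the largest organic component
  expect_equal(write_smiles(standardize(parse_smiles("[Na+].CC(=O)[O-]"))),
               write_smiles(parse_smiles("CC(=O)O")))
  expect_equal(write_smiles(standardize(parse_smiles("Cl.NCCc1ccccc1"))),
               write_smiles(parse_smiles("NCCc1ccccc1")))
  # sulfoxides to the uncharged form
  expect_equal(write_smiles(standardize(parse_smiles("C[S+](C)[O-]"))),
               write_smiles(parse_smiles("CS(C)=O")))
  # organometallics are rejected; boronic acids survive
  g <- standardize(parse_smiles("CC[Mg]Br"))
  expect_s3_class(g, "ss_rejection")
  expect_equal(g$reason, "organometallic")
  expect_false(is_rejection(standardize(parse_smiles("OB(O)c1ccccc1"))))
})

test_that("the molecular-weight cutoff is strict at the cap", {
  m <- parse_smiles("CCCCCCCCCC")
  cap <- mol_mw(m)
  expect_false(is_rejection(standardize(m, mw_cap = cap)))     # = cap kept
  over <- standardize(m, mw_cap = cap - 0.01)                  # > cap out
  expect_s3_class(over, "ss_rejection")
  expect_equal(over$reason, "overweight")
})

test_that("standardize is idempotent over the fixture panel", {
  for (bb in toy_bbs()) {
    once <- standardize(bb)
    twice <- standardize(once)
    expect_equal(write_smiles(twice), write_smiles(once))
  }
})

test_that("the standardization report conserves counts", {
  toy_bbs()
  rep <- .world$std_report
  expect_equal(rep$input_count, rep$retained_count + nrow(rep$rejections))
  expect_true("organometallic" %in% rep$rejections$reason)
  expect_true("overweight" %in% rep$rejections$reason)
})

test_that("aromaticity models differ exactly on exocyclic double bonds", {
  pyridone <- parse_smiles("O=c1cccc[nH]1")
  expect_true(any(perceive_aromaticity(pyridone, "DEFAULT")$atoms$aromatic))
  expect_false(any(perceive_aromaticity(pyridone, "CACTVS")$atoms$aromatic))
  # CACTVS keeps alternating Kekulé orders so valences stay correct
  expect_true(check_valence(perceive_aromaticity(pyridone, "CACTVS")))
  benzene <- parse_smiles("C1=CC=CC=C1")
  expect_true(any(perceive_aromaticity(benzene, "DEFAULT")$atoms$aromatic))
  expect_true(any(perceive_aromaticity(benzene, "CACTVS")$atoms$aromatic))
  # exocyclic C=C breaks aromaticity under both models
  fulv <- parse_smiles("C=C1C=CC=CC1")
  expect_false(any(perceive_aromaticity(fulv, "DEFAULT")$atoms$aromatic))
  expect_false(any(perceive_aromaticity(fulv, "CACTVS")$atoms$aromatic))
  # O/N/S partner: aromatic under DEFAULT only
  thiopy <- parse_smiles("S=c1cccc[nH]1")
  expect_true(any(perceive_aromaticity(thiopy, "DEFAULT")$atoms$aromatic))
  expect_false(any(perceive_aromaticity(thiopy, "CACTVS")$atoms$aromatic))
})

test_that("models agree atom-by-atom without ring exocyclic double bonds", {
  for (bb in toy_bbs()) {
    ri <- with_rings(bb)
    has_exo <- FALSE
    in_ring <- logical(n_atoms(ri))
    for (r in synthonspace:::mol_rings(ri)) in_ring[r] <- TRUE
    b <- ri$bonds
    for (k in seq_len(nrow(b))) {
      if (b$order[k] == 2L && !b$ring[k] &&
          (in_ring[b$a1[k]] || in_ring[b$a2[k]])) has_exo <- TRUE
    }
    if (has_exo) next
    d <- perceive_aromaticity(bb, "DEFAULT")
    c <- perceive_aromaticity(bb, "CACTVS")
    expect_identical(d$atoms$aromatic, c$atoms$aromatic, label = bb$source_id)
  }
})

test_that("the valence model flags non-favored states", {
  expect_true(check_valence(parse_smiles("C")))
  expect_false(check_valence(parse_smiles("CN(C)(C)C")))   # uncharged N(IV)
  expect_true(check_valence(parse_smiles("C[N+](C)(C)C"))) # ammonium fine
  expect_true(check_valence(parse_smiles("CS(=O)(=O)C")))  # sulfone S(VI)
})

test_that("protecting groups come off exhaustively and precisely", {
  gly <- write_smiles(parse_smiles("NCC(=O)O"))
  r <- remove_protecting_groups(pmol("CC(C)(C)OC(=O)NCC(=O)O"))
  expect_equal(r$removed, "Boc")
  expect_equal(write_smiles(r$mol), gly)
  r <- remove_protecting_groups(pmol("O=C(O)CNC(=O)OCC1c2ccccc2-c2ccccc21"))
  expect_equal(r$removed, "Fmoc")
  expect_equal(write_smiles(r$mol), gly)
  r <- remove_protecting_groups(pmol("O=C(O)CNC(=O)OCc1ccccc1"))
  expect_equal(r$removed, "Cbz")
  expect_equal(write_smiles(r$mol), gly)
  r <- remove_protecting_groups(pmol("CC(C)(C)OC(=O)CN"))
  expect_equal(r$removed, "tBu-ester")
  expect_equal(write_smiles(r$mol), gly)
  r <- remove_protecting_groups(pmol("NCC(=O)OCc1ccccc1"))
  expect_equal(r$removed, "Bn-ester")
  expect_equal(write_smiles(r$mol), gly)
  r <- remove_protecting_groups(pmol("OCCOC(=O)c1ccccc1"))
  expect_equal(r$removed, "Bz-ester")
  expect_equal(write_smiles(r$mol), write_smiles(parse_smiles("OCCO")))
  # no protecting group: unchanged
  r <- remove_protecting_groups(pmol("NCCc1ccccc1"))
  expect_equal(r$removed, character(0))
  expect_equal(write_smiles(r$mol), write_smiles(pmol("NCCc1ccccc1")))
  # doubly protected amino-alcohol: both removed
  r <- remove_protecting_groups(pmol("CC(C)(C)OC(=O)NCCOC(C)(C)C"))
  expect_setequal(r$removed, c("Boc", "tBu-ether"))
  expect_equal(write_smiles(r$mol), write_smiles(parse_smiles("NCCO")))
})

test_that("deprotection conserves heavy atoms outside the matched group", {
  protected <- pmol("CC(C)(C)OC(=O)NCCc1ccccc1")
  r <- remove_protecting_groups(protected)
  # phenethylamine backbone: 8 heavy atoms survive untouched
  expect_equal(synthonspace:::heavy_atom_count(r$mol), 9L)
  expect_equal(write_smiles(r$mol), write_smiles(parse_smiles("NCCc1ccccc1")))
})

test_that("file readers parse SMILES and SDF V2000 alike", {
  tmp <- tempfile(fileext = ".smi")
  writeLines(c("CCO\tbb1", "CC(=O)O\tbb2", "not_a_smiles\tbb3"), tmp)
  mols <- read_building_blocks(tmp)
  expect_length(mols, 3L)
  expect_equal(mols[[1]]$source_id, "bb1")
  expect_s3_class(mols[[3]], "ss_rejection")
  expect_equal(mols[[3]]$reason, "parse_error")
  # SDF record: ethanol with explicit charge line
  sdf <- c("ethanol", "  synthon", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0",
           "    0.0000    0.0000    0.0000 C   0  0",
           "    0.0000    0.0000    0.0000 O   0  0",
           "  1  2  1  0", "  2  3  1  0",
           "M  END", "$$$$")
  tmp2 <- tempfile(fileext = ".sdf")
  writeLines(sdf, tmp2)
  mols2 <- read_building_blocks(tmp2)
  expect_length(mols2, 1L)
  expect_equal(write_smiles(mols2[[1]]), write_smiles(parse_smiles("CCO")))
})
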