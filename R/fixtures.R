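# Synthetic fixtures: seeded building-block panels, a toy transform
# suite covering every mechanism (plain coupling, ring formation with
# explicit product aromaticity, negated-fusion duplication,
# cross-reactant KILLs with GOTO, symmetric zero-product patterns), and
# the independent product-level brute-force oracle the test-suite pins
# the space machinery against.

#' Default fixture specification
#'
#' Counts per functional class plus adversarial fractions. Defaults are
#' sized like a miniature vendor catalogue slice: a few members per
#' reactive class and one or two of each adversarial case, enough to
#' exercise every filtering rule while keeping brute-force enumeration
#' instant.
#'
#' @param seed integer seed.
#' @return A list understood by [generate_building_blocks()].
#' @export
fixture_spec <- function(seed = 42L) {
  list(
    seed = seed,
    counts = list(
      primary_amines = 6L, secondary_amines = 3L, carboxylic_acids = 5L,
      aryl_halides = 4L, boronic_acids = 4L, alkynes = 2L, azides = 2L,
      alkenes = 3L, thioamides = 3L, bromoketones = 3L, alcohols = 3L
    ),
    adversarial = list(
      nitro_amines = 1L, boc_amines = 1L, organometallics = 1L,
      overweight = 1L, amino_acids = 1L, alpha_halo_acids = 1L,
      dihalo_ketones = 1L, aryl_thioamides = 1L, aryl_bromoketones = 1L,
      benzylic_amines = 1L, fused_aryl_halides = 1L
    )
  )
}

.fixture_templates <- list(
  primary_amines   = c("NCC", "NCCC", "NC1CCCC1", "NCCCC", "NCCc1ccccc1",
                       "NCCCCC", "NC(C)CC", "NCc1ccco1"),
  secondary_amines = c("CNCC", "CCNCC", "C1CCNCC1", "CNC1CCCC1"),
  carboxylic_acids = c("CC(=O)O", "CCC(=O)O", "OC(=O)c1ccccc1",
                       "OC(=O)C1CCC1", "CC(C)C(=O)O", "OC(=O)Cc1ccccc1"),
  aryl_halides     = c("Brc1ccccc1", "Brc1ccccc1C", "Brc1ccc(C)cc1",
                       "Brc1cccc(CC)c1", "Brc1ccc(OC)cc1"),
  boronic_acids    = c("OB(O)c1ccccc1", "OB(O)c1ccc(C)cc1", "OB(O)CC",
                       "OB(O)c1cccc(C)c1", "OB(O)C=C"),
  alkynes          = c("C#CCC", "C#Cc1ccccc1", "C#CCCC"),
  azides           = c("CCN=[N+]=[N-]", "CCCN=[N+]=[N-]",
                       "[N-]=[N+]=NCc1ccccc1"),
  alkenes          = c("C=CCC", "C=CCCC", "CC=CC", "C=Cc1ccccc1"),
  thioamides       = c("NC(=S)C", "NC(=S)CC", "NC(=S)C1CCC1",
                       "NC(=S)CCC"),
  bromoketones     = c("BrCC(=O)C", "BrCC(=O)CC", "BrCC(=O)C1CCC1",
                       "BrCC(=O)CCC"),
  alcohols         = c("OCC", "OCCC", "OCc1ccccc1"),
  # adversarial classes
  nitro_amines     = c("NCCC[N+](=O)[O-]"),
  boc_amines       = c("CC(C)(C)OC(=O)NCCN"),
  organometallics  = c("CC[Mg]Br"),
  overweight       = c(paste0("NCCC", strrep("c1ccc(cc1)c1ccc(cc1)", 5),
                              "CC(=O)O")),
  amino_acids      = c("NCCC(=O)O"),
  alpha_halo_acids = c("OC(=O)CBr"),
  dihalo_ketones   = c("BrCC(=O)CCl"),
  aryl_thioamides  = c("NC(=S)c1ccccc1"),
  aryl_bromoketones = c("BrCC(=O)c1ccccc1"),
  benzylic_amines  = c("NCc1ccccc1"),
  fused_aryl_halides = c("Brc1ccc2ccccc2c1")
)

#' Generate a synthetic building-block panel
#'
#' Deterministic for a fixed seed: class templates are recycled and, when
#' a class needs more members than it has templates, extended by homologation
#' (appending methylenes to a templated scaffold). Class labels are
#' returned as a sidecar for oracle tests.
#'
#' @param spec a [fixture_spec()] list.
#' @param path optional: write a SMILES file (`<path>.smi`) and a JSON
#'   sidecar (`<path>.json`).
#' @return Data frame with `smiles`, `id`, `class`.
#' @export
generate_building_blocks <- function(spec = fixture_spec(), path = NULL) {
  out <- list()
  withr_seed(spec$seed, {
    all_classes <- c(spec$counts, spec$adversarial)
    for (cls in names(all_classes)) {
      n <- all_classes[[cls]]
      if (n == 0L) next
      templates <- .fixture_templates[[cls]]
      if (is.null(templates)) stop("no templates for fixture class ", cls)
      smi <- character(n)
      for (t in seq_len(n)) {
        base <- templates[((t - 1L) %% length(templates)) + 1L]
        extra <- (t - 1L) %/% length(templates)
        # homologate deterministically when templates run out
        smi[t] <- if (extra > 0L) paste0(base, strrep("C", extra)) else base
      }
      out[[cls]] <- data.frame(smiles = smi,
                               id = sprintf("%s_%02d", cls, seq_len(n)),
                               class = cls)
    }
  })
  panel <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!is.null(path)) {
    writeLines(paste(panel$smiles, panel$id, sep = "\t"),
               paste0(path, ".smi"))
    jsonlite::write_json(panel, paste0(path, ".json"), auto_unbox = TRUE)
  }
  panel
}

#' The toy transform suite
#'
#' Five-plus transforms covering the mechanism matrix: a plain
#' two-component coupling (amide), a ring-forming condensation with an
#' aromatic product (thiazole), a biaryl coupling with a negated fusion
#' bond (variant duplication), a symmetric alkene pattern (zero products
#' under the SPACE policy), an amine arylation with a spectator-carbon
#' pattern (policy differentiation), and a GOTO-rescued amide variant.
#' Each entry bundles the transform text and its translated KILL ruleset.
#'
#' @return Named list of entries `list(id, text, kills)` where `kills` is
#'   the ruleset in schema form (pass to [load_kill_ruleset()]).
#' @export
toy_transform_suite <- function() {
  list(
    amide = list(
      id = 9001L,
      text = paste(
        "ID 9001",
        "NAME Toy amide coupling",
        "REACTANT N^1{HS>0}{HETS=0}{!FGS=AMIDE}",
        "REACTANT C^2(=O^3)-O{HS=1}",
        "PRODUCT N-C=O", sep = "\n"),
      kills = list(
        transform = 9001L,
        statements = list(
          list(index = 1L, smarts = list("[NX3+](=[OX1])[OX1-]"),
               scope = "ONPATH", participants = list(), goto = NULL),
          list(index = 2L, smarts = list("[102*][*][F,Cl,Br,I]"),
               scope = "OFFPATH", participants = list(2L), goto = NULL),
          list(index = 3L, smarts = list(),
               scope = "ONPATH", participants = list(1L), goto = NULL)
        ),
        untranslatable = list("LESS*HINDERED"))
    ),
    thiazole = list(
      id = 9002L,
      text = paste(
        "ID 9002",
        "NAME Toy Hantzsch thiazole synthesis",
        "REACTANT N^1{HS=2}-C^2(=S^3)",
        "REACTANT BR-C^4{HS=2}-C^5(=O)",
        "PRODUCT N%1=C-S-C=C%1", sep = "\n"),
      kills = list(
        transform = 9002L,
        statements = list(
          list(index = 1L,
               smarts = list("[102*;$([102*][c])]", "[105*;$([105*][c])]"),
               scope = "ONPATH", participants = list(2L, 5L), goto = 3L),
          list(index = 2L,
               smarts = list("[102*;$([102*][CH3])]", "[105*;$([105*][CH3])]"),
               scope = "ONPATH", participants = list(2L, 5L), goto = NULL),
          list(index = 3L, smarts = list("[104*][F,Cl,Br,I]"),
               scope = "OFFPATH", participants = list(4L), goto = NULL)
        ),
        untranslatable = list())
    ),
    biaryl_fusion = list(
      id = 9003L,
      text = paste(
        "ID 9003",
        "NAME Toy biaryl coupling with non-fused halide",
        "REACTANT BR-C^1{AROMATIC}:&!FUSION C^2{AROMATIC}{HS=1}",
        "REACTANT B(-O{HS=1})(-O{HS=1})-C^3{AROMATIC}",
        "PRODUCT C{AROMATIC}(:C{AROMATIC})-C{AROMATIC}", sep = "\n"),
      kills = list(transform = 9003L, statements = list(),
                   untranslatable = list())
    ),
    alkene_symmetric = list(
      id = 9004L,
      text = paste(
        "ID 9004",
        "NAME Toy alkene arylation (symmetric alkene pattern)",
        "REACTANT C^1=C^2{HS>0}",
        "REACTANT B(-O{HS=1})(-O{HS=1})-C^3{AROMATIC}",
        "PRODUCT C=C-C{AROMATIC}", sep = "\n"),
      kills = list(transform = 9004L, statements = list(),
                   untranslatable = list())
    ),
    chanlam = list(
      id = 9006L,
      text = paste(
        "ID 9006",
        "NAME Toy amine arylation (spectator-carbon pattern)",
        "REACTANT N^1{HS>0}{!FGS=AMIDE}-C^3",
        "REACTANT B(-O{HS=1})(-O{HS=1})-C^2{AROMATIC}",
        "PRODUCT N(-C{AROMATIC})-C", sep = "\n"),
      kills = list(transform = 9006L, statements = list(),
                   untranslatable = list())
    ),
    amide_goto = list(
      id = 9005L,
      text = paste(
        "ID 9005",
        "NAME Toy amide coupling with GOTO rescue",
        "REACTANT N^1{HS>0}{HETS=0}{!FGS=AMIDE}",
        "REACTANT C^2(=O^3)-O{HS=1}",
        "PRODUCT N-C=O", sep = "\n"),
      kills = list(
        transform = 9005L,
        statements = list(
          list(index = 1L, smarts = list("[101*][CX4][c]"),
               scope = "ONPATH", participants = list(1L), goto = 3L),
          list(index = 2L, smarts = list("[101*][CX4]"),
               scope = "ONPATH", participants = list(1L), goto = NULL),
          list(index = 3L, smarts = list("[NX3+](=[OX1])[OX1-]"),
               scope = "ONPATH", participants = list(), goto = NULL)
        ),
        untranslatable = list())
    )
  )
}

# --- independent product-level oracle ---------------------------------

# Assemble the product of a matched pair directly on the full molecules,
# keeping isotope labels on the core atoms. Used only by the oracle.
oracle_assemble <- function(rec1, rec2, rule, model, keep_labels = FALSE) {
  slots <- link_slots(rule)
  pins <- product_h_pins(rule)
  halves <- list()
  for (side in 1:2) {
    rec <- if (side == 1L) rec1 else rec2
    syn <- synthon_from_record(rec, rule, slots, pins, side, model,
                               default_valence_table())
    halves[[side]] <- syn
  }
  mol <- assemble_product(halves[[1]], halves[[2]], model)
  if (keep_labels) {
    # re-derive labels from a product-pattern embedding
    a <- smarts_match(mol, rule$product_pattern)
    if (length(a)) {
      maps <- vapply(rule$product_pattern$atoms, `[[`, 0L, "map")
      lab <- a[[1]][maps > 0L]
      mol$atoms$isotope[lab] <- .KILL_ISO_OFFSET + maps[maps > 0L]
    }
  }
  mol
}

# Product-level KILL traversal (library-style semantics): statements run
# on the labelled, unmasked product in index order; cross-side AND
# statements require all their side groups to match; OFFPATH patterns
# must not extend into labelled (on-path) atoms except through their own
# anchors.
oracle_product_killed <- function(product, ruleset, rule) {
  stmts <- ruleset$statements
  if (!length(stmts)) return(FALSE)
  indices <- vapply(stmts, `[[`, 0L, "index")
  infos <- lapply(stmts, statement_sides, side_of_map = rule$side_of_map)
  ctx <- mol_context(product)
  labelled <- which(product$atoms$isotope > .KILL_ISO_OFFSET)
  entry_hit <- function(pat) {
    hits <- smarts_match_ctx(pat, ctx)
    length(hits) > 0L
  }
  entry_hit_offpath <- function(pat) {
    anchors <- smarts_iso_labels(pat)
    for (a in smarts_match_ctx(pat, ctx)) {
      body <- a[!(a %in% labelled)]
      anchor_atoms <- a[a %in% labelled]
      # allowed labelled atoms: only the pattern's own anchors
      ok_anchors <- all(product$atoms$isotope[anchor_atoms] %in%
                          (.KILL_ISO_OFFSET + anchors))
      if (ok_anchors && length(body) + length(anchor_atoms) == length(a))
        return(TRUE)
    }
    FALSE
  }
  stmt_triggered <- function(t) {
    st <- stmts[[t]]
    if (!length(st$patterns)) return(FALSE)
    info <- infos[[t]]
    cross_and <- length(info$sides) == 2L &&
      any(vapply(info$entry_sides, function(e) 1L %in% e, TRUE)) &&
      any(vapply(info$entry_sides, function(e) 2L %in% e, TRUE))
    hit_one <- function(i) {
      if (st$scope == "OFFPATH") entry_hit_offpath(st$patterns[[i]])
      else entry_hit(st$patterns[[i]])
    }
    if (cross_and) {
      h1 <- FALSE; h2 <- FALSE
      for (i in seq_along(st$patterns)) {
        es <- info$entry_sides[[i]]
        h <- hit_one(i)
        if (1L %in% es && h) h1 <- TRUE
        if (2L %in% es && h) h2 <- TRUE
      }
      h1 && h2
    } else {
      any(vapply(seq_along(st$patterns), hit_one, TRUE))
    }
  }
  t <- 1L; guard <- 0L
  while (t <= length(stmts)) {
    guard <- guard + 1L
    if (guard > 10L * length(stmts)) stop("oracle: GOTO loop")
    if (stmt_triggered(t)) {
      gt <- stmts[[t]]$goto
      if (is.na(gt)) return(TRUE)
      t <- match(gt, indices)
    } else t <- t + 1L
  }
  FALSE
}

#' Brute-force product-level enumeration oracle
#'
#' The independent reference the space machinery is pinned against:
#' building blocks are matched under the single-match policy, every
#' surviving cross pair is assembled directly, and the KILL statements
#' are applied to each labelled product individually (library-style),
#' with no synthon encoding, signature grouping or sub-reaction
#' splitting involved.
#'
#' @param rules list of `ss_reaction_rule` (variants of one or more
#'   transforms).
#' @param bbs standardized, perceived building blocks.
#' @param rulesets named list of rulesets by transform id.
#' @param policy duplicate policy.
#' @param model aromaticity model.
#' @return Data frame: `transform_id`, `variant_tag`, `bb1`, `bb2`,
#'   `smiles`, `killed`.
#' @export
oracle_enumerate <- function(rules, bbs, rulesets = list(),
                             policy = "SPACE", model = "DEFAULT") {
  rows <- list()
  assigned <- new.env(parent = emptyenv())
  for (rule in rules) {
    ruleset <- rulesets[[as.character(rule$transform_id)]]
    if (is.null(ruleset))
      ruleset <- load_kill_ruleset(list(transform = rule$transform_id,
                                        statements = list(),
                                        untranslatable = list()))
    mres <- match_building_blocks(rule, bbs, policy, ruleset = ruleset)
    recs <- list(list(), list())
    for (rec in mres$records) {
      k <- paste(rule$transform_id, rec$pattern_side, rec$bb$source_id,
                 sep = "|")
      if (!is.null(assigned[[k]])) next
      # fragments are stored deprotected: mirror the pipeline's step
      dp <- remove_protecting_groups(rec$bb)
      if (length(dp$removed)) {
        rr <- match_building_blocks(rule, list(dp$mol), policy,
                                    ruleset = ruleset)
        if (length(rr$records) != 1L ||
            rr$records[[1]]$pattern_side != rec$pattern_side) next
        rec <- rr$records[[1]]
      }
      assigned[[k]] <- rule$variant_tag
      recs[[rec$pattern_side]] <- c(recs[[rec$pattern_side]], list(rec))
    }
    for (r1 in recs[[1]]) for (r2 in recs[[2]]) {
      prod <- tryCatch(
        oracle_assemble(r1, r2, rule, model, keep_labels = TRUE),
        error = function(e) NULL)
      if (is.null(prod)) next
      killed <- oracle_product_killed(prod, ruleset, rule)
      clean <- prod; clean$atoms$isotope[clean$atoms$isotope > .KILL_ISO_OFFSET] <- 0L
      rows[[length(rows) + 1L]] <- data.frame(
        transform_id = rule$transform_id, variant_tag = rule$variant_tag,
        bb1 = r1$bb$source_id, bb2 = r2$bb$source_id,
        smiles = write_smiles(clean), killed = killed)
    }
  }
  if (!length(rows)) {
    return(data.frame(transform_id = integer(), variant_tag = character(),
                      bb1 = character(), bb2 = character(),
                      smiles = character(), killed = logical()))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
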