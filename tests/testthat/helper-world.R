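# Shared fixture world, built once per test run. Everything is generated
# in code from the seeded fixture spec; no static data files.

.world <- new.env(parent = emptyenv())

toy_bbs <- function(model = "DEFAULT") {
  key <- paste0("bbs_", model)
  if (!is.null(.world[[key]])) return(.world[[key]])
  panel <- generate_building_blocks(fixture_spec())
  mols <- lapply(seq_len(nrow(panel)), function(i)
    parse_smiles(panel$smiles[i], name = panel$id[i],
                 source_id = panel$id[i]))
  std <- standardize_collection(mols)
  bbs <- lapply(std$mols, perceive_aromaticity, model = model)
  .world[[key]] <- bbs
  .world$panel <- panel
  .world$std_report <- std$report
  bbs
}

toy_panel <- function() {
  toy_bbs()
  .world$panel
}

toy_rules <- function(name) {
  key <- paste0("rules_", name)
  if (is.null(.world[[key]])) {
    .world[[key]] <- translate_transform(toy_transform_suite()[[name]]$text)
  }
  .world[[key]]
}

toy_ruleset <- function(name) {
  entry <- toy_transform_suite()[[name]]
  rs <- list(load_kill_ruleset(entry$kills))
  names(rs) <- as.character(entry$id)
  rs
}

toy_space <- function(name, policy = "SPACE", model = "DEFAULT") {
  key <- paste("space", name, policy, model, sep = "_")
  if (!is.null(.world[[key]])) return(.world[[key]])
  rules <- toy_rules(name)
  srs <- filter_building_blocks(rules, toy_bbs(model), policy = policy,
                                rulesets = toy_ruleset(name))
  sp <- build_space(srs, paste0("toy-", name), model = model,
                    policy = policy)
  attr(sp, "subreactions") <- srs
  .world[[key]] <- sp
  sp
}

toy_oracle <- function(name, policy = "SPACE", model = "DEFAULT") {
  key <- paste("oracle", name, policy, model, sep = "_")
  if (!is.null(.world[[key]])) return(.world[[key]])
  res <- oracle_enumerate(toy_rules(name), toy_bbs(model),
                          rulesets = toy_ruleset(name),
                          policy = policy, model = model)
  .world[[key]] <- res
  res
}

toy_enumeration <- function(name, policy = "SPACE", model = "DEFAULT") {
  key <- paste("enum", name, policy, model, sep = "_")
  if (!is.null(.world[[key]])) return(.world[[key]])
  e <- enumerate_products(toy_space(name, policy, model), limit = Inf,
                          seed = 1L)
  .world[[key]] <- e
  e
}

# single standardized+perceived molecule for ad-hoc checks
pmol <- function(smiles, model = "DEFAULT") {
  perceive_aromaticity(parse_smiles(smiles), model)
}

pmol_id <- function(smiles, id, model = "DEFAULT") {
  perceive_aromaticity(parse_smiles(smiles, name = id, source_id = id),
                       model)
}
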