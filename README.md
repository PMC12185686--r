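# synthonspace

Reaction-driven combinatorial fragment spaces from retrosynthetic
transform patterns, in pure R.

Make-on-demand virtual libraries are defined by robust two-component
reactions applied to catalogues of purchasable building blocks. Enumerated
they reach billions of products; encoded as a *fragment space* — synthons
(pre-processed reactant fragments with typed link atoms) plus per-reaction
connection rules — the same chemistry supports exact counting, seeded
sampling, membership tests and property histograms without materializing a
single product list.

This package implements the full construction pipeline for reaction
knowledge written in the LHASA-era CHMTRN/PATRAN pattern dialect:

* **Transpiler** — tokenizes transform patterns, builds node/edge pattern
  graphs, and translates them to reaction SMARTS through a data-driven
  keyword map (recursive functional-group environments, enumerated numeric
  ranges, fusion-bond variants, declarative per-transform adjustments).
* **Chemistry model** — building-block standardization (salt stripping,
  sulfoxide/carboxylate normalization, organometallic and overweight
  rejection), protecting-group removal (Boc, Fmoc, Cbz, tBu/benzyl esters,
  tBu ether, benzoate), a NAOMI-like valence model, and a switchable
  aromaticity model (`DEFAULT` vs `CACTVS`, which differ exactly on rings
  bearing exocyclic double bonds).
* **Reactant-level KILL filtering** — translated KILL rulesets (JSON) are
  applied to masked reactants: ONPATH statements see the reactant with the
  leaving group masked, OFFPATH statements additionally have the mapped
  backbone cut; GOTO statements redirect the walk, and cross-reactant
  statements split a reaction into sub-reactions so that within each one
  every reactant pair is valid.
* **Fragment space** — synthons with typed link atoms, one topology graph
  per sub-reaction, exact product counting, uniform seeded enumeration,
  retro-validation, exact membership by retro-decomposition, and
  bin-exact additive-property histograms by convolution.
* **Fixtures** — a seeded synthetic building-block generator and a toy
  transform corpus, pinned against a committed brute-force oracle that
  assembles every pair directly and applies KILLs per product.

The molecular core (SMILES reader/canonical writer, ring perception,
aromaticity models, SMARTS-subset matcher) is self-contained: the method's
semantics — aromaticity-neutral primitives, masks invisible to negated
primitives, isotope-slot map labels — live inside the matcher itself.

## Worked example

Build an amide-coupling fragment space from a handful of blocks:

```r
library(synthonspace)

bbs <- lapply(list(c("NCC", "amine1"), c("NCCC", "amine2"),
                   c("CC(=O)O", "acid1"), c("OC(=O)c1ccccc1", "acid2"),
                   c("OC(=O)CBr", "acid3")),
              function(x) perceive_aromaticity(
                parse_smiles(x[1], source_id = x[2]), "DEFAULT"))

entry <- toy_transform_suite()$amide
rules <- translate_transform(entry$text)
rules[[1]]
#> <rule 9001 'Toy amide coupling':
#>   [#7;H1,H2,H3,H4;!$([*](~[!#6;!#1]));!$([NX3][CX3]=[OX1]):1] .
#>   [#6:2](=[#8:3])-[#8;H1] >> [#7:1]-,:[#6:2]=,:[#8:3]>

rulesets <- setNames(list(load_kill_ruleset(entry$kills)), "9001")
srs <- filter_building_blocks(rules, bbs, policy = "SPACE",
                              rulesets = rulesets)
attr(srs, "exclusions")
#>   bb_id transform_id variant_tag   reason
#> 1 acid3         9001             killed:1

space <- build_space(srs, "amides", model = "DEFAULT")
space
#> <fragment space 'amides': 1 sub-reaction(s), 4 products (model DEFAULT)>
```

Two amines times two surviving acids (the α-bromo acid was vetoed by an
OFFPATH KILL statement) gives four products, counted without enumeration.
Enumerate them, test membership, profile the space:

```r
enumerate_products(space, limit = Inf, seed = 1)$smiles
#> [1] "C(C)(NCC)=O"         "C(c1ccccc1)(NCC)=O"
#> [3] "C(C)(NCCC)=O"        "C(c1ccccc1)(NCCC)=O"

space_contains(space, "CCNC(=O)c1ccccc1")[[1]][c("bb1", "bb2")]
#> $bb1
#> [1] "amine1"
#> $bb2
#> [1] "acid2"

h <- property_histograms(space, "MW")
sum(h$counts) == count_products(space)
#> [1] TRUE
```

`space_contains()` decomposes the query at the product pattern's formed
bond and looks the canonical pieces up in the synthon indexes — exact, no
fingerprints involved. The histogram is a discrete convolution of per-side
descriptor multisets: bin-exact, still enumeration-free.

A thin CLI wraps the same functions (`exec/synthonspace`): `translate`,
`build-space`, `count`, `enumerate`, `props`, `contains`, `coverage`,
`fixtures`.

## Acceptance script

`scripts/acceptance.R` rebuilds the whole fixture world from scratch with
the installed package — generates and standardizes the seeded
building-block panel, translates the toy transform corpus, applies the
KILL rulesets, builds the fragment space, counts it, samples it, and
verifies a membership round-trip — then writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

| Path | Contents |
| --- | --- |
| `R/` | molecular core, patran tokenizer, transpiler, KILL engine, reactant filter, fragment space, fixtures |
| `inst/extdata/` | grammar, keyword translation map (with its molecule panel), protecting-group table |
| `tests/testthat/` | unit + property tests per module, `test-acceptance.R` with the acceptance criteria |
| `scripts/acceptance.R` | end-to-end acceptance run |
| `vignettes/fragment-space-methods.Rmd` | the methods vignette: model, assumptions, numerical choices, limitations |
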