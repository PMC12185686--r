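---
title: "Methods: transform transpilation and combinatorial fragment spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transform transpilation and combinatorial fragment spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthonspace)
```

## The problem

Make-on-demand compound collections are built by applying robust,
two-component reactions to catalogues of purchasable building blocks.
Enumerated, such collections reach billions of structures and become
unsearchable; stored as a *combinatorial fragment space* — pre-processed
reactant fragments ("synthons") carrying typed link atoms, plus per-reaction
connection rules — the same chemistry fits in megabytes and supports exact
counting, sampling, membership testing and property profiling without ever
materializing the product list.

The reaction knowledge this package consumes is written in a
retrosynthesis-era pattern language (the CHMTRN/PATRAN dialect): each
*transform* holds structural patterns for the two reactants and the product,
and a list of procedural KILL statements that veto problematic substrates.
The package's job is to (1) transpile those patterns into reaction SMARTS,
(2) apply the KILL logic at the *reactant* level — products cannot be
filtered individually in a combinatorial store — and (3) encode the result
as a fragment space with exact, enumeration-free operations.

## Pipeline and assumptions

1. **Standardization** (`standardize()`): explicit hydrogens folded into
   implicit counts, disconnected metals/salts stripped (largest organic
   component kept; a component with no carbon, or only metal atoms, is a
   salt), charge-separated sulfoxides neutralized, carboxylates protonated,
   organometallics (any carbon–metal bond; boron, silicon and tin are not
   metals here so boronic acids survive) rejected, and molecules heavier
   than 700 g/mol rejected. The weight cutoff is strict (`>` 700) and is
   measured **before** deprotection, reading the cutoff as a property of the
   purchasable block, not of the fragment.
2. **Aromaticity** (`perceive_aromaticity()`): one model per pipeline run.
   `DEFAULT` counts Hückel electrons and keeps rings with exocyclic double
   bonds aromatic when the exocyclic partner is O, N or S (2-pyridone is
   aromatic); `CACTVS` declares any ring with an exocyclic double bond
   non-aromatic and leaves its bonds as alternating single/double orders, so
   valence states remain correct. Perception always starts from the Kekulé
   structure: switching models never changes connectivity or hydrogen
   counts, only flags.
3. **Transpilation** (`translate_transform()`): pattern text is tokenized by
   a table-driven grammar, built into a node/edge graph (branch levels from
   parentheses; ring-closure edges stored with start node after end node),
   and translated keyword-by-keyword through a data-file map. Atoms without
   an explicit aromaticity constraint are emitted as atomic-number
   primitives (`[#6]`), deliberately aromaticity-neutral so that the active
   perception model — not the pattern — decides matches. Open numeric ranges
   (`HS>1`) are enumerated up to 4, the maximal organic connectivity.
   Functional-group presence joins recursive SMARTS with OR, absence with
   AND of negations. Neighbouring-heteroatom counts become counted recursive
   environments.
4. **Fusion bonds**: SMARTS cannot state "this bond fuses two rings"; the
   property moves to the incident atoms (member of at least two smallest
   rings). For the *negated* property this atom encoding is contradictory if
   asserted on both ends, so each negated-fusion bond produces two pattern
   variants (annotation on one end, then the other). The encoding is a known
   approximation: on an angular three-ring aromatic the pattern finds three
   bonds where only two are true fusion bonds — the test-suite pins this
   false positive as expected behaviour rather than hiding it.
5. **Building-block selection**: the single-match rule (a block must match
   exactly one reactant pattern, exactly once) under two duplicate policies.
   `LIB2020` unifies embeddings that cover the same atom set; `SPACE`
   unifies embeddings that agree on the *reaction-centre* atoms (mapped
   atoms that form, lose or change bonds), so symmetric double matches that
   would give the same product count once while genuine product mixtures
   exclude the block. A block matching both sides is excluded unless every
   match of one side is killed, in which case the surviving side is kept.
6. **KILL evaluation**: each matched reactant is prepared twice — variant
   (a) with the leaving group replaced by dummy masks and the backbone
   labelled with map numbers through the isotope slot (offset +100), and
   variant (b) with every bond among labelled atoms cut. ONPATH statements
   run on (a), OFFPATH on (b), so OFFPATH patterns cannot run along the
   reaction substructure. Dummy atoms never match any SMARTS primitive
   except an explicit `#0`, so negated primitives cannot "see" a mask.
   Statements are walked in index order; GOTO redirects, a trigger without
   GOTO kills. Statements that depend on the partner reactant branch the
   walk; the nested list of possible paths is the reactant's signature.
7. **Sub-reaction splitting**: reactants with equal signatures form groups;
   groups are paired when the cross-reactant statements allow every pair,
   and side-1 groups with identical partner sets merge. Pairs are covered
   exactly once. Cross statements whose SMARTS name mapped atoms of both
   sides are conjunctions (both side-local conditions must hold);
   statements with unlabelled SMARTS are "anywhere" disjunctions.
8. **Synthons and the space**: leaving atoms (plus dangling substituents)
   are deleted, same-side bond orders set to their product values, typed
   link dummies attached (link type = slot index in the isotope field), and
   hydrogen counts adjusted by bond-order conservation — or pinned where the
   product pattern states `{HS=n}`. A fragment whose implied product
   environment violates the valence model (pentavalent carbon, uncharged
   tetravalent nitrogen) is dropped with a reason. One topology graph per
   sub-reaction: two synthon sets, one edge.

## Exact operations without enumeration

* `count_products()` sums `|side1| x |side2|` per graph. R doubles hold
  integers exactly to 2^53; the implementation raises an error beyond that
  rather than rounding (published spaces reach ~1e10, five orders below the
  limit). An arbitrary-precision integer type was not available in the
  target environment; exactness, the actual requirement, is preserved.
* `enumerate_products()` samples pair indices uniformly without replacement
  from the concatenated pair lattice, seeded; `limit >= count` is a full,
  deterministic enumeration. Products are assembled by joining link atoms
  and re-perceiving aromaticity, and an assembly-time valence failure is a
  hard error by design: invalid combinations must have been excluded
  earlier.
* `space_contains()` cuts the query at every embedding of a sub-reaction's
  product pattern, canonicalizes the two pieces with their typed dummies,
  and looks them up in the synthon key indexes — exact by construction, one
  provenance per route.
* `retro_validate()` is the same cut plus the requirement that the pieces
  equal the recorded reactants' synthons.
* `property_histograms()` convolves per-side value multisets for additive
  descriptors (MW; H-bond donors/acceptors; an acyclic-single-bond
  rotatable-bond proxy with a +1 link correction per formed acyclic single
  bond). The rotatable proxy is refused on ring-forming sub-reactions,
  where bonds change cyclicality at assembly and additivity genuinely
  fails — an error, not a silent approximation.

Product patterns are matched against *perceived* products, so the emitted
product SMARTS tolerate the aromatic flag on formed bonds (`-,:`, `=,:`).
Ring-forming products are assembled with the Kekulé orders the product
pattern states and then re-perceived; canonical SMILES of aromatic systems
are order-independent, so membership keys are stable. For rings with more
than one valid Kekulé assignment the acyclic pieces of a cut could in
principle disagree with the synthon's stored orders; the bundled toy
chemistry has unique assignments, and the round-trip tests would expose a
violation.

## The synthetic world

`generate_building_blocks()` emits a deterministic, seeded catalogue slice:
a few members per reactive class (amines, acids, aryl halides, boronic
acids, alkenes, alkynes, azides, thioamides, α-bromoketones, alcohols) and
one member per adversarial class — KILL triggers (nitro amines, α-halo
acids, dihalo ketones), protecting groups, an organometallic, an overweight
block, both-side matchers (amino acids), symmetric matchers, fused aryl
halides. Class sizes are small (49 blocks) so the committed brute-force
oracle — match, assemble every pair directly, apply KILLs to each labelled
product — stays instant; everything the filters can do is still exercised.
What the fixtures do **not** emulate: vendor-catalogue scale and skew,
stereochemistry, tautomerism, multi-step protections. A green suite
establishes that the combinatorial encoding equals product-level filtering
on this world, not that the chemistry model reproduces any specific vendor
library.

The toy transform corpus covers the mechanism matrix: plain coupling
(amide), ring formation with an aromatic product and two cross-reactant
KILL statements with a GOTO (thiazole condensation), negated-fusion
variant duplication (biaryl coupling), a symmetric pattern that the SPACE
policy must empty (alkene arylation), a spectator-carbon pattern separating
the two duplicate policies (amine arylation), and a GOTO-rescue amide
variant.

## Numerical and design choices

* Range enumeration cap 4; ring-distance constructs expand to at most six
  ring bonds (`kill_same_ring_smarts()`); the electron-withdrawing-group
  keyword expands to exactly four positional cases in the translation map.
* Untranslatable KILL keywords (e.g. steric comparisons) load as
  skip-with-warning entries: they never silently pass as matches, every
  skip is recorded in the signature.
* GOTO semantics: an absolute jump in the flat statement list; the walk
  guards against loops.
* A building block matched by two fusion variants of the same transform is
  assigned to the lowest-numbered variant only; the uniqueness oracle
  (no pair generated twice) enforces the choice.
* Product counts are **not** deduplicated across transforms or
  sub-reactions (reported counts are sums, matching how such spaces are
  reported); cross-route duplicates are visible through
  `space_contains()`, which returns one provenance per route.
* The CuAAC-style regiochemistry check is exercised on the thiazole
  regioisomer pair rather than on azide chemistry: the toy assembly
  machinery does not model the charge neutralization an azide cycloaddition
  implies, and the property under test — a product pattern rejecting the
  wrong regioisomer — is identical.
* MW boundary: exactly 700 g/mol is retained ("more than 700" is strict).
* Masks in variant (b) are produced by cutting bonds only; hydrogen counts
  of the cut atoms are left untouched so H-count primitives keep their
  reactant meaning.

## Known limitations

* The SMARTS engine implements the subset the corpus needs (elements,
  charges, isotopes, H/D/X/R/r, recursion, boolean operators, bond
  order/ring primitives); it has no stereo, component-level grouping, or
  `@`/`@@` chirality — stereoisomers are out of scope throughout.
* Ring perception keeps, per bond, the shortest cycle through it — adequate
  for the fused systems at hand, not a full SSSR for exotic cages.
* Reactant-level KILL filtering approximates product-level filtering; the
  equality holds on the bundled corpus, and the OFFPATH ring-context
  divergences documented for real corpora would appear as pinned
  differences in the oracle-equivalence tests, not as silent drift.
* clogP/TPSA are not additive over synthons without a fragment-contribution
  model and are deliberately unsupported in histograms.
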