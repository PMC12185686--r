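# Independent RDKit oracle, driven through the system python. Used only
# to cross-check the package's own SMILES/SMARTS machinery on small
# panels; never as the implementation.

rdkit_available <- function() {
  if (!is.null(.world$rdkit_ok)) return(.world$rdkit_ok)
  ok <- tryCatch({
    out <- suppressWarnings(system2("python",
      c("-c", shQuote("import rdkit; print('ok')")),
      stdout = TRUE, stderr = FALSE))
    identical(tail(out, 1), "ok")
  }, error = function(e) FALSE)
  .world$rdkit_ok <- ok
  ok
}

# canonical SMILES (and optionally N random rewrites) for a vector of
# SMILES; returns a list with $canonical and $random (list of vectors)
rdkit_canonical <- function(smiles, n_random = 0L) {
  input <- jsonlite::toJSON(list(smiles = I(smiles), n_random = n_random),
                            auto_unbox = TRUE)
  script <- '
import sys, json
from rdkit import Chem
spec = json.load(sys.stdin)
out = {"canonical": [], "random": []}
for s in spec["smiles"]:
    m = Chem.MolFromSmiles(s)
    out["canonical"].append(Chem.MolToSmiles(m) if m else None)
    rs = []
    if m and spec["n_random"] > 0:
        for i in range(spec["n_random"]):
            rs.append(Chem.MolToSmiles(m, doRandom=True, canonical=False))
    out["random"].append(rs)
json.dump(out, sys.stdout)
'
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 input = as.character(input), stderr = FALSE)
  jsonlite::fromJSON(paste(res, collapse = ""), simplifyVector = FALSE)
}

# has-match booleans for (smarts, smiles) pairs
rdkit_hasmatch <- function(smarts, smiles) {
  input <- jsonlite::toJSON(list(smarts = I(smarts), smiles = I(smiles)),
                            auto_unbox = TRUE)
  script <- '
import sys, json
from rdkit import Chem
spec = json.load(sys.stdin)
out = []
for p, s in zip(spec["smarts"], spec["smiles"]):
    patt = Chem.MolFromSmarts(p)
    mol = Chem.MolFromSmiles(s)
    out.append(bool(mol.HasSubstructMatch(patt)) if (patt and mol) else None)
json.dump(out, sys.stdout)
'
  res <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 input = as.character(input), stderr = FALSE)
  unlist(jsonlite::fromJSON(paste(res, collapse = "")))
}
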