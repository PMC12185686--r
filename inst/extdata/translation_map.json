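{
  "comment": [
    "Keyword-to-SMARTS translation map. Functional-group templates are",
    "anchored: the first pattern atom is the atom carrying the property;",
    "the transpiler wraps each template in a recursive $(...) and joins",
    "presence with OR / absence with AND-of-negations. Every entry ships",
    "a positive/negative molecule panel which the test-suite matches",
    "against the wrapped template — the semantic-equivalence harness."
  ],
  "bonds": { "-": "-", "=": "=", "#": "#", ":": ":", "~": "~" },
  "bond_properties": {
    "RINGBOND": { "bond_append": "@" },
    "FUSION": {
      "atom_annotation": "!R0;!R1",
      "negated_annotation": "$([R0]),$([R1])"
    }
  },
  "het_smarts": "[!#6;!#1]",
  "functional_groups": {
    "CARBOXYL": {
      "smarts": ["[CX3](=[OX1])[OX2;H1]"],
      "positive": ["CC(=O)O", "OC(=O)c1ccccc1"],
      "negative": ["CCO", "CC(=O)OC", "CC(=O)N"]
    },
    "PRIMARY_AMINE": {
      "smarts": ["[NX3;H2;!$([NX3][CX3]=[OX1])]"],
      "positive": ["CCN", "Nc1ccccc1"],
      "negative": ["CNC", "CC(=O)N", "C[N+](C)(C)C"]
    },
    "SECONDARY_AMINE": {
      "smarts": ["[NX3;H1;!$([NX3][CX3]=[OX1])]"],
      "positive": ["CNC", "C1CCNC1"],
      "negative": ["CCN", "CN(C)C", "CC(=O)NC"]
    },
    "AMINE": {
      "smarts": ["[NX3;H2;!$([NX3][CX3]=[OX1])]",
                 "[NX3;H1;!$([NX3][CX3]=[OX1])]"],
      "positive": ["CCN", "CNC"],
      "negative": ["CN(C)C", "CC(=O)N"]
    },
    "KETONE": {
      "smarts": ["[CX3](=[OX1])([#6])[#6]"],
      "positive": ["CC(=O)C"],
      "negative": ["CC=O", "CC(=O)O"]
    },
    "ALDEHYDE": {
      "smarts": ["[CX3;H1]=[OX1]"],
      "positive": ["CC=O"],
      "negative": ["CC(=O)C", "CC(=O)O"]
    },
    "HYDROXYL": {
      "smarts": ["[OX2;H1;!$([OX2;H1][CX3]=[OX1])]"],
      "positive": ["CCO", "Oc1ccccc1"],
      "negative": ["CC(=O)O", "CC(=O)OC", "COC"]
    },
    "THIOL": {
      "smarts": ["[SX2;H1]"],
      "positive": ["CCS"],
      "negative": ["CSC", "CS(=O)C"]
    },
    "HALIDE": {
      "smarts": ["[F,Cl,Br,I]"],
      "positive": ["CCBr", "Clc1ccccc1"],
      "negative": ["CCO", "CCN"]
    },
    "BORONIC": {
      "smarts": ["[BX3]([OX2])[OX2]"],
      "positive": ["OB(O)c1ccccc1", "CB(O)O"],
      "negative": ["CCO", "OCO"]
    },
    "AZIDE": {
      "smarts": ["[NX2;$([NX2]=[NX2+]=[NX1-])]"],
      "positive": ["CCN=[N+]=[N-]"],
      "negative": ["CCN", "CCC#N"]
    },
    "ALKYNE_TERMINAL": {
      "smarts": ["[CX2;H1]#[CX2]"],
      "positive": ["C#CCC"],
      "negative": ["CC#CC", "C=CC"]
    },
    "ALKENE": {
      "smarts": ["[CX3]=[CX3]"],
      "positive": ["C=CC"],
      "negative": ["CCC", "c1ccccc1"]
    },
    "AMIDE": {
      "smarts": ["[NX3][CX3]=[OX1]"],
      "positive": ["CC(=O)NC"],
      "negative": ["CCN", "CC(=O)OC"]
    },
    "ESTER": {
      "smarts": ["[CX3](=[OX1])[OX2][#6]"],
      "positive": ["CC(=O)OC"],
      "negative": ["CC(=O)O", "CC(=O)NC"]
    },
    "NITRO": {
      "smarts": ["[NX3+](=[OX1])[OX1-]"],
      "positive": ["CC[N+](=O)[O-]"],
      "negative": ["CCN", "CC(=O)N"]
    },
    "CYANO": {
      "smarts": ["[CX2]#[NX1]"],
      "positive": ["CCC#N"],
      "negative": ["CCN", "CC#CC"]
    },
    "WITHDRAWING": {
      "comment": "bond-property keyword: an atom bonded to one of exactly four electron-withdrawing group positions",
      "smarts": ["[*][CX3]=[OX1]",
                 "[*][CX2]#[NX1]",
                 "[*][NX3+](=[OX1])[OX1-]",
                 "[*][SX4](=[OX1])=[OX1]"],
      "anchored_neighbour": true,
      "positive": ["CC(=O)C", "CCC#N", "CC[N+](=O)[O-]", "CCS(=O)(=O)C"],
      "negative": ["CCO", "CCC"]
    }
  }
}
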