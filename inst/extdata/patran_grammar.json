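{
  "comment": [
    "Micro-grammar for the PATRAN-style pattern dialect accepted by the",
    "tokenizer. The tokenizer is table-driven: token classes are tried in",
    "order, longest-alternative first. Conventions fixed here (the source",
    "language leaves them open): atom tokens are element names from the",
    "`atoms` map, optionally carrying a circumflex atom map (C^1);",
    "atom properties follow their atom in braces, e.g. {HS=2}, {HS>0},",
    "{HETS<2}, {FGS=CARBOXYL,KETONE}, {!FGS=AMIDE}, {CHARGE=+1},",
    "{AROMATIC}; bond properties follow their bond symbol as &WORD or",
    "&!WORD (&FUSION, &!FUSION, &RINGBOND); branches use parentheses;",
    "ring closures use %d referring to a matching earlier %d."
  ],
  "atoms": {
    "CARBON": "C", "NITROGEN": "N", "OXYGEN": "O", "SULFUR": "S",
    "PHOSPHORUS": "P", "BORON": "B", "FLUORINE": "F", "CHLORINE": "Cl",
    "BROMINE": "Br", "IODINE": "I",
    "CL": "Cl", "BR": "Br",
    "C": "C", "N": "N", "O": "O", "S": "S", "P": "P", "B": "B",
    "F": "F", "I": "I",
    "X": "*", "ANY": "*"
  },
  "bonds": { "-": "-", "=": "=", "#": "#", ":": ":", "~": "~" },
  "atom_properties": ["HS", "HETS", "CHARGE", "FGS", "AROMATIC",
                      "ALIPHATIC", "RING"],
  "bond_properties": ["FUSION", "RINGBOND"],
  "range_cap": 4
}
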