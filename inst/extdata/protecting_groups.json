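{
  "comment": "Protecting-group removal table. `smarts` is anchored so atom 1 is the protected heteroatom that survives; `delete` lists 1-based pattern atom indices removed; `add_h` hydrogens are restored on atom 1. Order matters only for reporting.",
  "groups": [
    {
      "name": "Boc",
      "class": "amino",
      "smarts": "[NX3][CX3](=[OX1])[OX2][CX4]([CH3])([CH3])[CH3]",
      "delete": [
        2,
        3,
        4,
        5,
        6,
        7,
        8
      ],
      "add_h": 1
    },
    {
      "name": "Fmoc",
      "class": "amino",
      "smarts": "[NX3][CX3](=[OX1])[OX2][CH2][CH1]1[c]2[cH][cH][cH][cH][c]2[c]2[cH][cH][cH][cH][c]12",
      "delete": [
        2,
        3,
        4,
        5,
        6,
        7,
        8,
        9,
        10,
        11,
        12,
        13,
        14,
        15,
        16,
        17,
        18
      ],
      "add_h": 1
    },
    {
      "name": "Cbz",
      "class": "amino",
      "smarts": "[NX3][CX3](=[OX1])[OX2][CH2][c]1[cH][cH][cH][cH][cH]1",
      "delete": [
        2,
        3,
        4,
        5,
        6,
        7,
        8,
        9,
        10,
        11
      ],
      "add_h": 1
    },
    {
      "name": "tBu-ester",
      "class": "carboxyl",
      "smarts": "[OX2;$([OX2][CX3](=[OX1])[#6])][CX4]([CH3])([CH3])[CH3]",
      "delete": [
        2,
        3,
        4,
        5
      ],
      "add_h": 1
    },
    {
      "name": "Bn-ester",
      "class": "carboxyl",
      "smarts": "[OX2;$([OX2][CX3](=[OX1])[#6])][CH2][c]1[cH][cH][cH][cH][cH]1",
      "delete": [
        2,
        3,
        4,
        5,
        6,
        7,
        8
      ],
      "add_h": 1
    },
    {
      "name": "tBu-ether",
      "class": "hydroxyl",
      "smarts": "[OX2;H0;!$([OX2][CX3]=[OX1])][CX4]([CH3])([CH3])[CH3]",
      "delete": [
        2,
        3,
        4,
        5
      ],
      "add_h": 1
    },
    {
      "name": "Bz-ester",
      "class": "hydroxyl",
      "smarts": "[OX2;H0;!$([OX2][CX4]([CH3])([CH3])[CH3])][CX3](=[OX1])[c]1[cH][cH][cH][cH][cH]1",
      "delete": [
        2,
        3,
        4,
        5,
        6,
        7,
        8,
        9
      ],
      "add_h": 1
    }
  ]
}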