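{
  "schema": "wireframeDNA-enzyme-table-1",
  "enzymes": [
    {"name": "AclI",    "site": "AACGTT", "cut5": 2},
    {"name": "BamHI",   "site": "GGATCC", "cut5": 1},
    {"name": "BsiWI",   "site": "CGTACG", "cut5": 1},
    {"name": "BstZ17I", "site": "GTATAC", "cut5": 3},
    {"name": "EcoRI",   "site": "GAATTC", "cut5": 1},
    {"name": "HindIII", "site": "AAGCTT", "cut5": 1},
    {"name": "MfeI",    "site": "CAATTG", "cut5": 1},
    {"name": "MluI",    "site": "ACGCGT", "cut5": 1}
  ]
}
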