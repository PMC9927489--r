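{
  "protein": "mdut",
  "comment": "M. tuberculosis trimeric dUTPase; key residues in author numbering. Motif intervals are bundled conventions around the key residues (interval edges are not printed in the primary literature).",
  "motifs": [
    {"id": "I",   "from": 20,  "to": 30,  "keys": []},
    {"id": "II",  "from": 60,  "to": 70,  "keys": [{"resno": 64, "aa": "R"}, {"resno": 65, "aa": "S"}]},
    {"id": "III", "from": 78,  "to": 90,  "keys": [{"resno": 83, "aa": "D"}, {"resno": 86, "aa": "Y"}]},
    {"id": "IV",  "from": 105, "to": 115, "keys": [{"resno": 110, "aa": "R"}]},
    {"id": "V",   "from": 127, "to": 154, "keys": [{"resno": 135, "aa": "H"}]}
  ]
}
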