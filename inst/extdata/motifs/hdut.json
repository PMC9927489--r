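{
  "protein": "hdut",
  "comment": "Human trimeric dUTPase (common nuclear/mitochondrial region, numbering as used with the solved complex). Motif V is the C-terminal P-loop that embraces Stl.",
  "motifs": [
    {"id": "I",   "from": 18,  "to": 28,  "keys": []},
    {"id": "II",  "from": 58,  "to": 68,  "keys": [{"resno": 62, "aa": "R"}, {"resno": 63, "aa": "S"}]},
    {"id": "III", "from": 74,  "to": 86,  "keys": [{"resno": 79, "aa": "D"}, {"resno": 82, "aa": "Y"}]},
    {"id": "IV",  "from": 100, "to": 110, "keys": [{"resno": 105, "aa": "R"}]},
    {"id": "V",   "from": 124, "to": 141, "keys": [{"resno": 127, "aa": "D"}, {"resno": 130, "aa": "R"}, {"resno": 133, "aa": "G"}, {"resno": 134, "aa": "G"}, {"resno": 136, "aa": "G"}]}
  ]
}
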