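{
  "protein": "ebvdut",
  "comment": "Epstein-Barr virus monomeric dUTPase. Monomeric Duts arose by gene triplication with sequence reshuffling, so the catalytic motifs are not in I-to-V order along the chain; only motifs with residues named in the Dut-Stl modelling are listed.",
  "reshuffled": true,
  "motifs": [
    {"id": "III", "from": 70,  "to": 80,  "keys": [{"resno": 73, "aa": "Y"}, {"resno": 76, "aa": "D"}]},
    {"id": "II",  "from": 165, "to": 178, "keys": [{"resno": 171, "aa": "R"}, {"resno": 172, "aa": "S"}]},
    {"id": "IV",  "from": 275, "to": 285, "keys": [{"resno": 280, "aa": "R"}]}
  ]
}
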