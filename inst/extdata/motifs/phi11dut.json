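{
  "protein": "phi11dut",
  "comment": "S. aureus phage phi11 trimeric dUTPase; carries the phage-specific motif VI insertion between motifs IV and V, hence the wide IV interval.",
  "motifs": [
    {"id": "I",   "from": 25,  "to": 35,  "keys": []},
    {"id": "II",  "from": 60,  "to": 70,  "keys": [{"resno": 64, "aa": "R"}, {"resno": 65, "aa": "S"}]},
    {"id": "III", "from": 77,  "to": 88,  "keys": [{"resno": 81, "aa": "D"}, {"resno": 84, "aa": "Y"}]},
    {"id": "IV",  "from": 128, "to": 138, "keys": [{"resno": 133, "aa": "K"}]},
    {"id": "V",   "from": 150, "to": 165, "keys": []}
  ]
}
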