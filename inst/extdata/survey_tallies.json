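{
  "classified": 1305,
  "chs23b": 32,
  "unclassified": 234,
  "total_stated": 1571,
  "excluded": 310,
  "retained_stated": 1261,
  "b1_division3": 95,
  "b1_excluded": 199,
  "b1_total_stated": 294,
  "head_to_head_with_intervening": 17,
  "head_to_head_without_intervening": 78,
  "head_to_head_species_stated": 95,
  "outgroup_division1_clade": 45,
  "outgroup_division2_clade": 37,
  "outgroup_total_stated": 82
}
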