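{
  "tag_map": {
    "Na": "NOUN",
    "Nb": "NOUN",
    "Nc": "NOUN",
    "Ncd": "NOUN",
    "Nd": "NOUN",
    "Nv": "NOUN",
    "Nh": "PRON",
    "VA": "VERB",
    "VAC": "VERB",
    "VB": "VERB",
    "VC": "VERB",
    "VCL": "VERB",
    "VD": "VERB",
    "VE": "VERB",
    "VF": "VERB",
    "VG": "VERB",
    "VH": "VERB",
    "VHC": "VERB",
    "VI": "VERB",
    "VJ": "VERB",
    "VK": "VERB",
    "VL": "VERB",
    "V_2": "VERB",
    "A": "ADJ",
    "D": "ADV",
    "Da": "ADV",
    "Dfa": "ADV",
    "Dfb": "ADV",
    "Di": "ADV",
    "Dk": "ADV",
    "P": "OTHER",
    "T": "OTHER",
    "I": "OTHER",
    "C": "OTHER",
    "Caa": "OTHER",
    "Cab": "OTHER",
    "Cba": "OTHER",
    "Cbb": "OTHER",
    "DE": "OTHER",
    "SHI": "OTHER",
    "FW": "OTHER",
    "Neu": "OTHER",
    "Nes": "OTHER",
    "Nep": "OTHER",
    "Neqa": "OTHER",
    "Neqb": "OTHER",
    "Nf": "OTHER",
    "Ng": "OTHER"
  },
  "bei_forms": "被",
  "ba_forms": "把",
  "filler_forms": ["呃", "喯", "啊", "嗯"]
}
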