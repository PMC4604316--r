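{
  "n_R": 4,
  "n_E": 15,
  "venn_counts": {
    "core": 3255,
    "all_R_some_E": 731,
    "some_R_all_E": 52,
    "some_some": 3157,
    "R_only": 268,
    "E_only": 3212
  },
  "reaction_counts": {
    "core": 1151,
    "shared": 175,
    "R_only": 1,
    "E_only": 105
  },
  "n_compounds": 190,
  "classes": [
    {"name": "carboxylic_acids",            "size": 45, "frac_R": 0.55, "frac_E": 0.35},
    {"name": "amino_acids",                 "size": 30, "frac_R": 0.55, "frac_E": 0.35},
    {"name": "substituted_monosaccharides", "size": 15, "frac_R": 0.55, "frac_E": 0.35},
    {"name": "sugar_alcohols",              "size": 15, "frac_R": 0.55, "frac_E": 0.35},
    {"name": "peptides",                    "size": 15, "frac_R": 0.25, "frac_E": 0.55},
    {"name": "sugar_acids",                 "size": 10, "frac_R": 0.25, "frac_E": 0.55},
    {"name": "nucleosides",                 "size": 10, "frac_R": 0.25, "frac_E": 0.55},
    {"name": "monosaccharides",             "size": 25, "frac_R": 0.25, "frac_E": 0.55},
    {"name": "miscellaneous",               "size": 25, "frac_R": 0.25, "frac_E": 0.55}
  ],
  "traits": [
    {"name": "siderophore",            "prev_R": 1.0,  "prev_E": 0.93},
    {"name": "phosphate_solubilization", "prev_R": 0.25, "prev_E": 0.53},
    {"name": "denitrification",        "prev_R": 0.0,  "prev_E": 0.27},
    {"name": "protease",               "prev_R": 0.5,  "prev_E": 0.73},
    {"name": "hcn_production",         "prev_R": 0.25, "prev_E": 0.53},
    {"name": "trehalose_uptake",       "prev_R": 0.5,  "prev_E": 0.67}
  ],
  "marker_length": 1500,
  "mu": 0.006,
  "prediction_error_rate": 0.24
}
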