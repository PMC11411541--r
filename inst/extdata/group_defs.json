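{
  "comment": "Group and bond definitions for the vector group-contribution fragmentation. First-order groups partition the heavy atoms (resolved by descending priority); second-order groups are additive corrections for halogenated carbons and claim no atoms. Bond SMARTS are ordered pairs written from the higher-electronegativity atom to the lower; fixed_zero bonds carry a dipole contribution pinned at zero.",
  "groups": [
    {"id": "CH3",     "order": 1, "smarts": "[CX4H3]",              "heavy_atoms": 1, "priority": 10},
    {"id": "CH2",     "order": 1, "smarts": "[CX4H2]",              "heavy_atoms": 1, "priority": 10},
    {"id": ">CH",     "order": 1, "smarts": "[CX4H1]",              "heavy_atoms": 1, "priority": 10},
    {"id": ">C<",     "order": 1, "smarts": "[CX4H0]",              "heavy_atoms": 1, "priority": 10},
    {"id": "=CH2",    "order": 1, "smarts": "[CX3H2]",              "heavy_atoms": 1, "priority": 10},
    {"id": "=CH",     "order": 1, "smarts": "[CX3H1]",              "heavy_atoms": 1, "priority": 10},
    {"id": "=C<",     "order": 1, "smarts": "[CX3H0]",              "heavy_atoms": 1, "priority": 10},
    {"id": "aldehyde","order": 1, "smarts": "[CX3H1]=[OX1]",        "heavy_atoms": 2, "priority": 50},
    {"id": "ketone",  "order": 1, "smarts": "[CX3H0]=[OX1]",        "heavy_atoms": 2, "priority": 49},
    {"id": "ether",   "order": 1, "smarts": "[OX2]",                "heavy_atoms": 1, "priority": 30},
    {"id": "formate", "order": 1, "smarts": "[OX2][CX3H1]=[OX1]",   "heavy_atoms": 3, "priority": 60},
    {"id": "ester",   "order": 1, "smarts": "[OX2][CX3H0]=[OX1]",   "heavy_atoms": 3, "priority": 59},
    {"id": "F",       "order": 1, "smarts": "[F]",                  "heavy_atoms": 1, "priority": 20},
    {"id": "Cl",      "order": 1, "smarts": "[Cl]",                 "heavy_atoms": 1, "priority": 20},
    {"id": "Br",      "order": 1, "smarts": "[Br]",                 "heavy_atoms": 1, "priority": 20},
    {"id": "I",       "order": 1, "smarts": "[I]",                  "heavy_atoms": 1, "priority": 20},
    {"id": "CH2(X)",  "order": 2, "smarts": "[CX4H2](C)[F,Cl,Br,I]",                          "heavy_atoms": 0, "priority": 0},
    {"id": ">CH(X)",  "order": 2, "smarts": "[CX4H1](C)(C)[F,Cl,Br,I]",                       "heavy_atoms": 0, "priority": 0},
    {"id": "CH(X2)",  "order": 2, "smarts": "[CX4H1](C)([F,Cl,Br,I])[F,Cl,Br,I]",             "heavy_atoms": 0, "priority": 0},
    {"id": ">C<(X)",  "order": 2, "smarts": "[CX4H0](C)(C)(C)[F,Cl,Br,I]",                    "heavy_atoms": 0, "priority": 0},
    {"id": ">C<(X2)", "order": 2, "smarts": "[CX4H0](C)(C)([F,Cl,Br,I])[F,Cl,Br,I]",          "heavy_atoms": 0, "priority": 0},
    {"id": "C(X3)",   "order": 2, "smarts": "[CX4H0](C)([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]","heavy_atoms": 0, "priority": 0},
    {"id": "=CH(X)",  "order": 2, "smarts": "[CX3H1](=C)[F,Cl,Br,I]",                         "heavy_atoms": 0, "priority": 0},
    {"id": "=C<(X)",  "order": 2, "smarts": "[CX3H0](=C)(C)[F,Cl,Br,I]",                      "heavy_atoms": 0, "priority": 0},
    {"id": "=C<(X2)", "order": 2, "smarts": "[CX3H0](=C)([F,Cl,Br,I])[F,Cl,Br,I]",            "heavy_atoms": 0, "priority": 0}
  ],
  "bonds": [
    {"id": "C-H",        "smarts": "[C][H]",      "fixed_zero": true},
    {"id": "Csp2-Csp3",  "smarts": "[CX3][CX4]",  "fixed_zero": true},
    {"id": "O-C",        "smarts": "[OX2][C]",    "fixed_zero": false},
    {"id": "O=C",        "smarts": "[OX1]=[C]",   "fixed_zero": false},
    {"id": "F-C",        "smarts": "[F][C]",      "fixed_zero": false},
    {"id": "Cl-C",       "smarts": "[Cl][C]",     "fixed_zero": false},
    {"id": "Br-C",       "smarts": "[Br][C]",     "fixed_zero": false},
    {"id": "I-C",        "smarts": "[I][C]",      "fixed_zero": false}
  ]
}
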