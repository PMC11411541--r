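{
  "metadata": {
    "provenance": "SYNTHETIC demonstration table. Carbon groups are the adopted homo-GC contributions; all oxygen/halogen group contributions, second-order corrections and bond dipole moments are synthetic stand-ins chosen from classical bond-dipole magnitudes and plausible segment sizes. They are NOT regressed to experimental data and serve as ground truth for the package's simulation studies.",
    "version": "1.0-synthetic"
  },
  "groups": [
    {"id": "CH3",     "m": 0.61198,  "sigma": 3.7202,  "epsilon_k": 229.90},
    {"id": "CH2",     "m": 0.45606,  "sigma": 3.8900,  "epsilon_k": 239.01},
    {"id": ">CH",     "m": 0.14304,  "sigma": 4.8597,  "epsilon_k": 347.64},
    {"id": ">C<",     "m": -0.66997, "sigma": -1.7878, "epsilon_k": 107.68},
    {"id": "=CH2",    "m": 0.36939,  "sigma": 4.0264,  "epsilon_k": 289.49},
    {"id": "=CH",     "m": 0.56361,  "sigma": 3.5519,  "epsilon_k": 216.69},
    {"id": "=C<",     "m": 0.86367,  "sigma": 3.1815,  "epsilon_k": 156.31},
    {"id": "ether",   "m": 0.30,     "sigma": 2.90,    "epsilon_k": 190.0},
    {"id": "aldehyde","m": 1.00,     "sigma": 3.25,    "epsilon_k": 270.0},
    {"id": "ketone",  "m": 0.90,     "sigma": 3.10,    "epsilon_k": 280.0},
    {"id": "formate", "m": 1.35,     "sigma": 3.30,    "epsilon_k": 260.0},
    {"id": "ester",   "m": 1.30,     "sigma": 3.25,    "epsilon_k": 265.0},
    {"id": "F",       "m": 0.40,     "sigma": 2.80,    "epsilon_k": 120.0},
    {"id": "Cl",      "m": 0.55,     "sigma": 3.30,    "epsilon_k": 310.0},
    {"id": "Br",      "m": 0.60,     "sigma": 3.50,    "epsilon_k": 390.0},
    {"id": "I",       "m": 0.65,     "sigma": 3.70,    "epsilon_k": 470.0},
    {"id": "CH2(X)",  "m": -0.05,    "sigma": 3.20,    "epsilon_k": 60.0},
    {"id": ">CH(X)",  "m": 0.06,     "sigma": 3.00,    "epsilon_k": 80.0},
    {"id": "CH(X2)",  "m": -0.08,    "sigma": 3.10,    "epsilon_k": 70.0},
    {"id": ">C<(X)",  "m": 0.07,     "sigma": 2.90,    "epsilon_k": 90.0},
    {"id": ">C<(X2)", "m": 0.09,     "sigma": 3.00,    "epsilon_k": 60.0},
    {"id": "C(X3)",   "m": -0.06,    "sigma": 3.40,    "epsilon_k": 80.0},
    {"id": "=CH(X)",  "m": 0.05,     "sigma": 3.10,    "epsilon_k": 75.0},
    {"id": "=C<(X)",  "m": -0.04,    "sigma": 3.30,    "epsilon_k": 65.0},
    {"id": "=C<(X2)", "m": 0.08,     "sigma": 2.95,    "epsilon_k": 85.0}
  ],
  "bonds": [
    {"id": "C-H",       "mu": 0.0},
    {"id": "Csp2-Csp3", "mu": 0.0},
    {"id": "O-C",       "mu": 1.10},
    {"id": "O=C",       "mu": 2.60},
    {"id": "F-C",       "mu": 1.70},
    {"id": "Cl-C",      "mu": 1.90},
    {"id": "Br-C",      "mu": 1.70},
    {"id": "I-C",       "mu": 1.50}
  ]
}
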