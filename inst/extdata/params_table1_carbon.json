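{
  "metadata": {
    "provenance": "Adopted homosegmented-GC carbon group contributions (alkane/alkene building blocks); hydrocarbon bonds carry zero dipole contribution by construction.",
    "version": "1.0"
  },
  "groups": [
    {"id": "CH3",  "m": 0.61198, "sigma": 3.7202,  "epsilon_k": 229.90},
    {"id": "CH2",  "m": 0.45606, "sigma": 3.8900,  "epsilon_k": 239.01},
    {"id": ">CH",  "m": 0.14304, "sigma": 4.8597,  "epsilon_k": 347.64},
    {"id": ">C<",  "m": -0.66997, "sigma": -1.7878, "epsilon_k": 107.68},
    {"id": "=CH2", "m": 0.36939, "sigma": 4.0264,  "epsilon_k": 289.49},
    {"id": "=CH",  "m": 0.56361, "sigma": 3.5519,  "epsilon_k": 216.69},
    {"id": "=C<",  "m": 0.86367, "sigma": 3.1815,  "epsilon_k": 156.31}
  ],
  "bonds": [
    {"id": "C-H",       "mu": 0.0},
    {"id": "Csp2-Csp3", "mu": 0.0}
  ]
}
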