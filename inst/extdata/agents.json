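[
  {"name": "SonoVue",  "gas": "SF6",   "chi_n_m": 0.22, "gamma": 1.0934, "sigma_n_m": 0.052, "kappa_m2_n": 9.173e-06},
  {"name": "Sonazoid", "gas": "C4F10", "chi_n_m": 0.53, "gamma": 1.0699, "sigma_n_m": 0.042, "kappa_m2_n": 6.537e-06},
  {"name": "Optison",  "gas": "C3F8",  "chi_n_m": 4.00, "gamma": 1.0731, "sigma_n_m": 0.900, "kappa_m2_n": 7.458e-06}
]
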