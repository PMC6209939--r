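{
  "glycerine90": {
    "comment": "90% glycerine-water immersion liquid. Anchor (eps1,eps2) at 1.2 GHz is measured; eps_inf and tau are plausible Debye assumptions, not measurements.",
    "anchor_freq_hz": 1.2e9,
    "anchor_eps1": 14.2,
    "anchor_eps2": 13.3,
    "eps_inf": 5.0,
    "tau_ps": 35.0
  },
  "water": {
    "comment": "Water target liquid. Anchor measured at 1.2 GHz; eps_inf/tau near literature values for room-temperature water.",
    "anchor_freq_hz": 1.2e9,
    "anchor_eps1": 78.6,
    "anchor_eps2": 4.8,
    "eps_inf": 5.2,
    "tau_ps": 8.3
  },
  "saltwater10": {
    "comment": "Salt-water 10 mg/mL target liquid. Anchor measured at 1.2 GHz; eps_inf/tau as for water, added ionic conductivity absorbed in sigma_s.",
    "anchor_freq_hz": 1.2e9,
    "anchor_eps1": 77.5,
    "anchor_eps2": 30.5,
    "eps_inf": 5.2,
    "tau_ps": 8.3
  }
}
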