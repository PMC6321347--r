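{
  "schema": "mechkit-network/1",
  "reference": "A",
  "wells": {
    "A": {
      "label": "A",
      "energy_kcal": 0,
      "freqs_cm": [320, 866, 1412, 1958, 2504, 3050],
      "m_opt": 1,
      "sink": false
    },
    "B": {
      "label": "B",
      "energy_kcal": -20,
      "freqs_cm": [320, 866, 1412, 1958, 2504, 3050],
      "m_opt": 1,
      "sink": true
    },
    "C": {
      "label": "C",
      "energy_kcal": -25,
      "freqs_cm": [320, 866, 1412, 1958, 2504, 3050],
      "m_opt": 1,
      "sink": true
    }
  },
  "transition_states": {
    "TS1": {
      "label": "TS1",
      "energy_kcal": 30,
      "freqs_cm": [320, 1002, 1685, 2368, 3050],
      "m_opt": 1,
      "connects": ["A", "B"],
      "rate_fwd_s": 2
    },
    "TS2": {
      "label": "TS2",
      "energy_kcal": 31,
      "freqs_cm": [320, 1002, 1685, 2368, 3050],
      "m_opt": 1,
      "connects": ["A", "C"],
      "rate_fwd_s": 1
    }
  },
  "bimolecular": []
}
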