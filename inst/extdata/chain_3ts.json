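{
  "schema": "mechkit-network/1",
  "reference": "R",
  "wells": {
    "R": {
      "label": "R",
      "energy_kcal": 0,
      "freqs_cm": [320, 515, 710, 905, 1100, 1295, 1490, 1685, 1880, 2075, 2270, 2465, 2660, 2855, 3050],
      "m_opt": 1,
      "sink": false
    },
    "I1": {
      "label": "I1",
      "energy_kcal": 40,
      "freqs_cm": [320, 515, 710, 905, 1100, 1295, 1490, 1685, 1880, 2075, 2270, 2465, 2660, 2855, 3050],
      "m_opt": 1,
      "sink": false
    },
    "I2": {
      "label": "I2",
      "energy_kcal": 45,
      "freqs_cm": [320, 515, 710, 905, 1100, 1295, 1490, 1685, 1880, 2075, 2270, 2465, 2660, 2855, 3050],
      "m_opt": 1,
      "sink": false
    },
    "P": {
      "label": "P",
      "energy_kcal": 20,
      "freqs_cm": [320, 515, 710, 905, 1100, 1295, 1490, 1685, 1880, 2075, 2270, 2465, 2660, 2855, 3050],
      "m_opt": 1,
      "sink": true
    }
  },
  "transition_states": {
    "TS1": {
      "label": "TS1",
      "energy_kcal": 60,
      "freqs_cm": [320, 530, 740, 950, 1160, 1370, 1580, 1790, 2000, 2210, 2420, 2630, 2840, 3050],
      "m_opt": 1,
      "connects": ["R", "I1"],
      "imag_freq_cm": 1200
    },
    "TS2": {
      "label": "TS2",
      "energy_kcal": 65,
      "freqs_cm": [320, 530, 740, 950, 1160, 1370, 1580, 1790, 2000, 2210, 2420, 2630, 2840, 3050],
      "m_opt": 1,
      "connects": ["I1", "I2"],
      "imag_freq_cm": 900
    },
    "TS3": {
      "label": "TS3",
      "energy_kcal": 70,
      "freqs_cm": [320, 530, 740, 950, 1160, 1370, 1580, 1790, 2000, 2210, 2420, 2630, 2840, 3050],
      "m_opt": 1,
      "connects": ["I2", "P"],
      "imag_freq_cm": 1500
    }
  },
  "bimolecular": []
}
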