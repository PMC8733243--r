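[
  {"name": "animal", "n_positive": 7053, "n_negative": 218154},
  {"name": "plant", "n_positive": 2172, "n_negative": 114929},
  {"name": "human", "n_positive": 1406, "n_negative": 81228},
  {"name": "arabidopsis", "n_positive": 231, "n_negative": 28359},
  {"name": "virus", "n_positive": 237, "n_negative": 839}
]
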