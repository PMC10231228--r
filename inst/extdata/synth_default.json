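{
  "n_docs": {"AD": 200, "CTRL": 200},
  "filler_rate": {"AD": 0.15, "CTRL": 0.01},
  "pronoun_substitution_rate": {"AD": 0.3, "CTRL": 0.02},
  "seed_word_coverage": {"AD": 0.3, "CTRL": 0.8},
  "sentence_count": {
    "AD": {"mean": 5, "sd": 1.5, "min": 2},
    "CTRL": {"mean": 8, "sd": 2, "min": 3}
  },
  "words_per_sentence": {"mean": 7, "sd": 2, "min": 3},
  "seed_pick_prob": 0.6,
  "n_distractors": 200,
  "seed": 1
}
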