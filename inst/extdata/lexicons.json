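{
  "seed_words": ["boy", "girl", "woman", "cookie", "stool", "sink", "overflow", "fall", "window", "curtain", "plate", "cloth", "jar", "water", "cupboard", "dish", "kitchen", "garden", "take", "wash", "reach", "attention", "see"],
  "fillers": ["uh", "um"],
  "pronouns": ["he", "she"]
}
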