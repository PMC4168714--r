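{
  "comment": "Default conditional reactivity densities for SHAPE-like probing. Repo default, tune per protocol: paired sites concentrate near zero, unpaired sites are right-tailed with mean ~0.9.",
  "paired": {
    "family": "exponential",
    "params": { "rate": 6.6667 }
  },
  "unpaired": {
    "family": "gamma",
    "params": { "shape": 1.8, "scale": 0.5 }
  }
}
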