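{
  "name": "clone-inference-demo",
  "stages": ["synth_clones", "cluster", "filter", "tree"],
  "seed": 11,
  "synth_clones": {"example": true, "nMutationsPerClone": 40, "depthMean": 120},
  "cluster": {"burnIn": 150, "nSamples": 150},
  "filter": {"minClusterSize": 20},
  "tree": {"minMedianVaf": 0.02, "epsilon": 0.05}
}
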