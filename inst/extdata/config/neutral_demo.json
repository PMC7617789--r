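{
  "name": "neutral-voter-demo",
  "stages": ["synth_labels", "simulate", "voids", "fit"],
  "seed": 7,
  "synth_labels": {"nRows": 96, "nCols": 96, "fraction": 0.5},
  "simulate": {"nSweeps": 60, "mode": "neutral"},
  "voids": {"connectivity": 4, "minSize": 2},
  "fit": {"range": [2, 60]}
}
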