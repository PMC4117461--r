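{
  "model": { "p": 1.0253 },
  "solver": { "t_end": 2000 },
  "analysis": { "variable": "x", "window": [50, 1000] }
}
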