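{
  "grid_shape": [8, 8],
  "fs": 2034.5,
  "duration": 11,
  "conduction_speed": 0.1,
  "noise_sd": 0.05,
  "pulse_sd_ms": 10,
  "seed": 42,
  "drivers": [
    {
      "kind": "rotor",
      "origin": [4.5, 7.2],
      "period": 180,
      "chirality": 1
    }
  ]
}
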