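{
  "params": "eiko",
  "protocol": {"kind": "square_wave", "high": 780, "low": 520, "period_s": 120},
  "duration_min": 60,
  "output_step_s": 30,
  "seed": 1,
  "solver": {"rtol": 1e-08, "atol": 1e-10}
}
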