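# Default avalanche survival curve: probability of survival of a completely
# buried subject as a function of burial time, piecewise linear between knots.
# Hand digitization of the published Swiss accident-data curve shape: a high
# plateau during the asphyxia-free first ~10 min, a steep decline to ~35 min
# as victims with obstructed airways asphyxiate, and a low slowly-decaying
# plateau afterwards. Approximate by construction -- substitute your own
# digitization for quantitative work against a specific source.
version: "1.0"
name: swiss-survival-digitization
time_unit: min
knots:
  - {time_min: 0,   survival: 0.92}
  - {time_min: 10,  survival: 0.91}
  - {time_min: 35,  survival: 0.34}
  - {time_min: 60,  survival: 0.28}
  - {time_min: 90,  survival: 0.25}
  - {time_min: 130, survival: 0.12}
  - {time_min: 180, survival: 0.03}
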