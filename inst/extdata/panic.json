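{
  "m": 2,
  "n": 2,
  "A": [
    [-1, 0],
    [1, 0]
  ],
  "B": [
    [
      [0, 0],
      [0.20000000000000001, 0]
    ],
    [
      [0, 0],
      [-0.20000000000000001, 0]
    ]
  ],
  "C": [
    [
      [-10, 0],
      [0, 0]
    ],
    [
      [10, 0],
      [0, 0]
    ]
  ],
  "D": [
    [0, 1],
    [0, -1]
  ],
  "relaxed": false,
  "name": "panic_model",
  "demography": {
    "beta": [
      [10, 0],
      [0, 0]
    ],
    "lam": [0, 0],
    "mu": [0, 0],
    "gamma": [
      [0, 0],
      [0, 0]
    ],
    "delta": [0, 0],
    "prey_offspring": [0, 1],
    "pred_offspring": [1, 0]
  }
}
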