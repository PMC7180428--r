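{
  "description": "Published cross-tabulation of two observers' Pfirrmann grades over 300 lumbar intervertebral discs (60 patients x 5 discs). Rows: observer 1 grade G1-G5; columns: observer 2.",
  "counts": [
    [6, 1, 0, 0, 0],
    [0, 83, 12, 0, 0],
    [0, 6, 84, 5, 0],
    [0, 0, 1, 66, 7],
    [0, 0, 0, 3, 26]
  ],
  "n_total": 300
}
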