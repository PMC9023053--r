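{
  "v_segments": {
    "TRBV-T": "TGTGCCAGC"
  },
  "j_segments": {
    "TRBJ-T": "TTTTTC"
  },
  "v_deletion_dist": 1,
  "j_deletion_dist": 1,
  "insertion_length_dist": [0.4, 0.1, 0.1, 0.4],
  "insertion_base_probs": {
    "A": 0.5,
    "C": 0,
    "G": 0.5,
    "T": 0
  },
  "vj_usage": [
    {
      "v": "TRBV-T",
      "j": "TRBJ-T",
      "prob": 1
    }
  ]
}
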