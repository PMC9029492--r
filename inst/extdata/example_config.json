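{
  "preset": "cofe2o4_gcd",
  "epsilon": 0.15,
  "T_K": 300,
  "H_kA_per_m": [5, 50, 100],
  "f_kHz": [50, 500, 1000],
  "D_max_nm": 30
}
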