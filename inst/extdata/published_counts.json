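{
  "called_wt": 12280,
  "called_ko": 12123,
  "unique_wt": 519,
  "unique_ko": 362,
  "differential_wt": 769,
  "differential_ko": 625,
  "peaks_wt": 15233,
  "peaks_ko": 14936,
  "de_wt": 503,
  "de_ko": 592,
  "unique_overlap_wt": 26,
  "unique_overlap_ko": 31,
  "differential_overlap_wt": 87,
  "differential_overlap_ko": 64
}
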