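sample	raw_reads	low_quality	mapped_reads	unique_mapped_reads	clean_rate	mapped_rate	unique_mapped_rate
wt_h3k4me3	12000000	35624	10836399	9244322	99.70	90.57	77.27
wt_input	12000000	60362	11536532	9098237	99.50	96.62	76.20
ko_h3k4me3	12000000	26598	11358011	9591198	99.78	94.86	80.10
ko_input	12000000	64237	11586545	9416926	99.46	97.07	78.90
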