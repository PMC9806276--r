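speed_kmh,n_total,n_identified,n_hit
2,87,83,79
3,145,134,125
4,103,89,82
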