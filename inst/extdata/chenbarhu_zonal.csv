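class,area_1e4_hm2,mean_gc_m2
lowland_meadow,29.36,52.75
temperate_meadow,63.43,63.02
temperate_typical,63.74,32.83
sandy,11.61,29.17
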