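# QC thresholds
maf_min = 0.05
hwe_p_min = 1e-5
yield_min = 0.95
info_min = 0.9
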