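# example configuration for the synthetic amino-acid dataset
corrections = proton-loss, na, obm
checks = missing, intensity
intensity_min = 0
intensity_max = 1e12
leading_boundary = 1
replicate_groups = 3, 3
output_formats = tsv, ftbl-ms, openflux
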