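chromatogram	obm
chrom_001	0.2
chrom_002	0.2
chrom_003	0.2
chrom_004	0.2
chrom_005	0.2
chrom_006	0.2
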