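region	observed_dcm	observed_gnomad
Z-disk	17	33
Proximal I-band	43	71
Distal I-band	44	35
Pre-exon 327 A-band	176	516
Exon 327	166	101
Post-exon 327 A-band	90	90
M-band	34	111
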