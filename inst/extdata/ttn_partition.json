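{
  "Z-disk": [1, 28],
  "Proximal I-band": [29, 50],
  "Distal I-band": [220, 252],
  "Pre-exon 327 A-band": [253, 326],
  "Exon 327": [327, 327],
  "Post-exon 327 A-band": [328, 358],
  "M-band": [359, 363]
}
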