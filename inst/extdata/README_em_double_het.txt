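em_double_het.tsv: one hom-ref/hom-ref individual and one double-het.
Expected EM frequencies: 00 -> 0.75, 11 -> 0.25, 01 -> 0, 10 -> 0.
Expected best pair for ind2: (00, 11) with posterior 1.0.
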