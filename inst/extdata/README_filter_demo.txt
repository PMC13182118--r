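filter_demo.vcf: 5 SNVs, 4 samples, thresholds 3 reads / QUAL 20 / MQ 20 / >=2 carriers.
Expected kept: 6:85646000:A>G, 6:85646300:T>C, 6:85646400:A>C (3 variants).
Expected removed: 6:85646100:C>T (qual), 6:85646200:G>A (carriers).
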