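chr1	999	1899	TOY1:span
chr1	1099	1200	TOY1
chr1	1599	1700	TOY1
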