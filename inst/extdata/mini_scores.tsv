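variant_id	tool	wt_score	mut_score
chr1:1500:A:G	maxent	8.0	4.0
chr1:1500:A:G	hsf	82.5	70.1
chr1:1500:A:G	nnsplice	0.95	0.40
chr1:1650:C:T	maxent	3.1	3.0
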