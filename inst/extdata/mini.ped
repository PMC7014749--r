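FAM1	S1	S2	S3	2	2	1	1
FAM1	S2	0	0	1	1	1	1
FAM1	S3	0	0	2	1	1	1
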