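##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description="Population minor allele frequency">
##INFO=<ID=GNOMAD_NHOMALT,Number=A,Type=Integer,Description="Population homozygote count">
##INFO=<ID=CLNSIG,Number=1,Type=String,Description="ClinVar clinical significance">
##INFO=<ID=CLNDN,Number=1,Type=String,Description="ClinVar phenotype list">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
chr1	1500	.	A	G	50	PASS	GENE=TOY1;GNOMAD_AF=0.0002;GNOMAD_NHOMALT=0;CLNSIG=Pathogenic;CLNDN=Retinitis_pigmentosa	GT	0/1	0/0	./.
chr1	1650	.	C	T,G	50	PASS	GENE=TOY1;GNOMAD_AF=0.001,0.2	GT	0/1	1/2	0/2
chr1	9000	rs1	T	C	50	PASS	GNOMAD_AF=0.45	GT	1/1	0/1	0/0
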