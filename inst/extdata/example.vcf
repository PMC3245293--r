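##fileformat=VCFv4.2
##source=synthetic example cohort (four individuals, four markers)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	ind1	ind2	ind3	ind4
1	1000	rs1	A	G	.	PASS	.	GT	0/0	0/0	0/1	1/1
1	2000	rs2	C	T	.	PASS	.	GT	1/1	1/1	0/1	1/1
1	3000	rs3	G	A	.	PASS	.	GT	0/1	0/1	0/1	0/1
2	500	rs4	T	C	.	PASS	.	GT	0/0	./.	0/1	0/0
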