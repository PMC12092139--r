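##fileformat=VCFv4.2
##INFO=<ID=LOC,Number=1,Type=String,Description="Locus group">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02
loc1	10	snp1	A	T	.	PASS	LOC=loc1	GT	0/0	0|1
loc1	42	snp2	C	G	.	PASS	LOC=loc1	GT	1|1	0/1
loc2	7	snp3	G	A	.	PASS	LOC=loc2	GT	./.	1/1
loc3	5	snp4	T	C,G	.	PASS	LOC=loc3	GT	0/1	0/0
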