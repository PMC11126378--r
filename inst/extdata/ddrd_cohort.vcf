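##fileformat=VCFv4.2
##source=founderseg fixture: five-carrier cohort around the index variant at chr1:21839005 (G>A). Marker positions, zygosity patterns and breaker sites transcribed from the published report; filler marker alleles and interleaved uninformative sites are synthetic.
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	DDRD_P02	DDRD_P03	DDRD_P04	DDRD_P06	DDRD_P07
1	21770500	.	T	C	.	.	.	GT	0/0	./.	0/1	0/0	0/0
1	21773254	.	T	C	.	.	.	GT	0/1	./.	./.	./.	./.
1	21774210	.	G	A	.	.	.	GT	0/0	0/0	0/1	0/1	0/0
1	21775527	.	C	T	.	.	.	GT	1/1	1/1	0/1	0/1	0/1
1	21780011	.	A	G	.	.	.	GT	1/1	./.	0/1	0/1	0/1
1	21790442	.	G	C	.	.	.	GT	1/1	1/1	0/1	1/1	0/1
1	21800000	.	T	A	.	.	.	GT	0/0	0/0	0/1	0/0	0/0
1	21810333	.	C	G	.	.	.	GT	1/1	1/1	0/1	0/1	0/1
1	21815500	.	A	AACACAC	.	.	.	GT	1/1	1/1	0/1	0/1	0/1
1	21820777	.	A	C	.	.	.	GT	./.	./.	0/1	0/1	./.
1	21830155	.	G	T	.	.	.	GT	1/1	1/1	1/1	0/1	0/1
1	21839005	rs1294413650	G	A	.	.	.	GT	1/1	1/1	0/1	0/1	0/1
1	21845001	.	C	T	.	.	.	GT	1/1	1/1	0/1	0/1	1/1
1	21852900	.	T	C	.	.	.	GT	1/1	./.	./.	0/1	0/1
1	21861499	.	A	G	.	.	.	GT	1/1	1/1	0/1	0/1	0/1
1	21862100	.	C	A	.	.	.	GT	0/0	0/0	0/1	0/0	0/0
1	21862954	.	G	A	.	.	.	GT	1/1	1/1	0/1	0/0	0/1
1	21865002	.	T	G	.	.	.	GT	1/1	1/1	0/1	0/1	0/1
1	21870100	.	A	T	.	.	.	GT	0/1	0/0	0/0	0/0	0/0
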