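snp_id	chromosome	allele_ref	allele_alt	uns_ref	uns_alt	orientation	as_read	ploidy	maf	allelic_or	group
rs1016343	8	C	T	TTCCCTCCCA	TTCCCTCTCA	reverse	FALSE	2	0.21	1.25	quadruplex
rs10993994	10	C	T	TGACGTCGAA	TGATGTCGAA	forward	TRUE	2	0.47	1.23	quadruplex
rs16901979	8	A	C	ATCTGGCAAA	CTCTGGCAAA	forward	TRUE	2	0.18	1.44	quadruplex
rs5945619	X	C	T	ACTCCCGCCG	ACTCCCGCTG	reverse	FALSE	1	0.26	1.23	quadruplex
rs10896449	11	A	G	GCTGAAAATT	GCTGAAAGTT	reverse	FALSE	2	0.40	0.84	quintuplex
rs1859962	17	T	G	TGATGAACAC	GGATGAACAC	forward	TRUE	2	0.39	1.19	quintuplex
rs4242382	8	A	G	CCACAGGCCC	CCGCAGGCCC	forward	TRUE	2	0.16	1.40	quintuplex
rs4430796	17	G	A	GATGCTGCAT	AATGCTGCAT	forward	TRUE	2	0.46	0.80	quintuplex
rs6983267	8	G	T	TGAAAGGCAC	TGAAAGTCAC	reverse	FALSE	2	0.43	0.81	quintuplex
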