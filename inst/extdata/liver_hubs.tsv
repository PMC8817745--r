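rank	symbol
1	GAPDH
2	TP53
3	EGFR
4	MYC
5	INS
6	ALB
7	IL6
8	AKT1
9	VEGFA
10	CDH1
11	PTEN
12	EGF
13	CDKN2A
14	KRAS
15	ESR1
16	CCND1
17	ERBB2
18	HRAS
19	STAT3
20	CASP3
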