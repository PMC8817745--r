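rank	symbol
1	TP53
2	HRAS
3	KRAS
4	CDKN2A
5	EGFR
6	EGF
7	ERBB2
8	AKT1
9	MYC
10	VEGFA
11	CDH1
12	GAPDH
13	ESR1
14	INS
15	PTEN
16	IL6
17	ALB
18	CCND1
19	NOTCH1
20	CTNNB1
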