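symbol	k_liver	k_pancreas
GAPDH	82	77
TP53	82	84
EGFR	80	81
MYC	80	78
INS	79	76
ALB	79	74
IL6	78	75
AKT1	78	78
VEGFA	78	78
CDH1	76	77
PTEN	75	76
EGF	75	79
CDKN2A	75	81
KRAS	73	82
ESR1	73	76
CCND1	72	72
ERBB2	72	79
HRAS	76	83
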