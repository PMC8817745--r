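item_id_a	item_id_b	mode	action	is_directional	a_is_acting
INS	ALB	expression	positive	t	t
INS	ALB	activation	positive	t	t
TP53	GAPDH	expression	positive	t	t
TP53	GAPDH	activation	positive	t	t
ESR1	GAPDH	activation	positive	t	t
INS	GAPDH	activation	positive	t	t
AKT1	TP53	expression	positive	t	t
AKT1	TP53	expression	negative	t	t
AKT1	TP53	inhibition	negative	t	t
IL6	TP53	expression	positive	t	t
CDKN2A	TP53	inhibition	negative	t	t
CDKN2A	TP53	activation	positive	t	t
ERBB2	TP53	activation	positive	t	t
TP53	PTEN	activation	positive	t	t
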