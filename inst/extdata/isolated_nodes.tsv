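map	symbol
expression	VEGFA
expression	MYC
activation	VEGFA
activation	MYC
inhibition	ESR1
inhibition	ERBB2
inhibition	IL6
inhibition	PTEN
inhibition	ALB
inhibition	MYC
inhibition	VEGFA
inhibition	GAPDH
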