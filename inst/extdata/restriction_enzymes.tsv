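name	site	offset
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
DpnII	GATC	0
AluI	AGCT	2
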