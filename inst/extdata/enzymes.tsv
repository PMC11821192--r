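name	pattern	cut_offset
RsaI	GTAC	2
AluI	AGCT	2
HaeIII	GGCC	2
DraI	TTTAAA	3
EcoRV	GATATC	3
SspI	AATATT	3
MboI	GATC	0
TaqI	TCGA	1
MseI	TTAA	1
HinfI	GANTC	1
DdeI	CTNAG	1
EcoRI	GAATTC	1
HindIII	AAGCTT	1
BamHI	GGATCC	1
AccI	GTMKAC	2
ApoI	RAATTY	1
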