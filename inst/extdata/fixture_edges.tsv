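gene_a	gene_b	label
EPHB6	ACACA	curated
ACACA	ENO3	experimental
ENO3	CARS	curated
CARS	ACAP2	experimental
TP73	BUB1B	curated
MEN1	CTBP2	predicted
RAD51	EPHB6	experimental
RAD51	ACACA	curated
RAD51	BRCA1	curated
RAD51	TP53	experimental
PRKAA1	ACACA	curated
PRKAA1	ENO3	co-expression
PRKAA1	CARS	predicted
BRCA1	TP53	curated
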