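gene	cdna	protein	case1	case2	case3	case4	rna_effect	expression_class	loh	consequence	chrom	pos	ref	alt
ACAP2	c.C976T	p.R326X	1	0	0	0	1	TUMOR_UP	0	nonsense	1	1001000	C	T
ACTL6A	c.T673A	p.S225T	1	0	0	0	0	NO_CHANGE	0	nonsynonymous_snv	2	1002000	T	A
BUB1B	c.T2609C	p.V870A	1	0	0	0	1	TUMOR_DOWN	1	nonsynonymous_snv	3	1003000	T	C
DDX11	c.G814A	p.V272M	1	0	0	0	0	NO_CHANGE	0	nonsynonymous_snv	4	1004000	G	A
EPB41	c.G1264A	p.E422K	1	0	0	0	0	NO_CHANGE	0	nonsynonymous_snv	5	1005000	G	A
MEN1	c.G301A	p.V101I	1	0	0	0	1	TUMOR_DOWN	1	nonsynonymous_snv	6	1006000	G	A
ACACA	c.C1948T	p.R650W	0	1	0	0	1	TUMOR_DOWN	1	nonsynonymous_snv	7	1007000	C	T
AMIGO3	c.C669A	p.C223X	0	1	0	0	1	BOTH_DOWN	0	nonsense	8	1008000	C	A
AVL9	c.37_38del	p.R13fs	0	1	0	0	0	NO_CHANGE	0	frameshift_indel	9	1009000	ACA	A
CTBP2	c.C2149T	p.R717C	0	1	0	0	0	NO_CHANGE	0	nonsynonymous_snv	10	1010000	C	T
CTSZ	c.G358A	p.V120M	0	1	0	0	0	NO_CHANGE	0	nonsynonymous_snv	11	1011000	G	A
DEPTOR	c.A631T	p.R211X	0	1	0	0	1	BOTH_DOWN	0	nonsense	12	1012000	A	T
ENO3	c.C642G	p.Y214X	0	1	0	0	1	TUMOR_UP	0	nonsense	13	1013000	C	G
GRM1	c.C2185A	p.P729T	0	1	0	0	0	NO_CHANGE	0	nonsynonymous_snv	14	1014000	C	A
MYO10	c.C5690T	p.S1897F	0	1	0	0	0	NO_CHANGE	0	nonsynonymous_snv	15	1015000	C	T
PFKP	c.G311A	p.R104Q	0	1	0	0	0	NO_CHANGE	0	nonsynonymous_snv	16	1016000	G	A
PSCA	c.G326A	p.W109X	0	1	0	0	1	TUMOR_UP	0	nonsense	17	1017000	G	A
ROCK1	c.C727T	p.P243S	0	1	0	0	0	NO_CHANGE	0	nonsynonymous_snv	18	1018000	C	T
WWTR1	c.1199_1200insTTTA	p.L400_X401delinsLX	0	1	0	0	1	TUMOR_DOWN	1	frameshift_indel	19	1019000	A	ATTTA
CARS	c.G775A	p.G259S	0	1	1	0	1	BOTH_DOWN	0	nonsynonymous_snv	20	1020000	G	A
ANGPTL4	c.637delC	p.P213fs	0	0	1	0	1	TUMOR_DOWN	1	frameshift_indel	21	1021000	AC	A
CUX1	c.2413dupC	p.G804fs	0	0	1	0	0	NO_CHANGE	0	frameshift_indel	22	1022000	A	AC
EPHB6	c.840delC	p.S280fs	0	0	1	0	0	NO_CHANGE	0	frameshift_indel	1	1023000	AC	A
FBN2	c.G3883A	p.D1295N	0	0	1	0	1	TUMOR_DOWN	1	nonsynonymous_snv	2	1024000	G	A
GANAB	c.C583T	p.R195C	0	0	1	0	0	NO_CHANGE	0	nonsynonymous_snv	3	1025000	C	T
KDM4C	c.3110delG	p.S1037fs	0	0	1	0	0	NO_CHANGE	0	frameshift_indel	4	1026000	AG	A
MMP14	c.C609A	p.Y203X	0	0	1	0	1	TUMOR_DOWN	1	nonsense	5	1027000	C	A
PTPN23	c.G4189T	p.G1397C	0	0	1	0	0	NO_CHANGE	0	nonsynonymous_snv	6	1028000	G	T
RNASEL	c.G793T	p.E265X	0	0	1	0	1	BOTH_DOWN	0	nonsense	7	1029000	G	T
TP73	c.G749T	p.G250V	0	0	1	0	1	TUMOR_DOWN	1	nonsynonymous_snv	8	1030000	G	T
ESRRA	c.C1162T	p.L388F	0	0	1	1	0	NO_CHANGE	0	nonsynonymous_snv	9	1031000	C	T
ESRRA	c.C1165T	p.R389C	0	0	1	1	0	NO_CHANGE	0	nonsynonymous_snv	10	1032000	C	T
ABHD5	c.G341T	p.R114L	0	0	0	1	0	NO_CHANGE	0	nonsynonymous_snv	11	1033000	G	T
ACAD9	c.G976A	p.A326T	0	0	0	1	0	NO_CHANGE	0	nonsynonymous_snv	12	1034000	G	A
EPHA7	c.A2009C	p.Q670P	0	0	0	1	0	NO_CHANGE	0	nonsynonymous_snv	13	1035000	A	C
EPN3	c.879delA	p.L293fs	0	0	0	1	0	NO_CHANGE	0	frameshift_indel	14	1036000	AA	A
IQGAP2	c.G1135C	p.E379Q	0	0	0	1	1	BOTH_DOWN	1	nonsynonymous_snv	15	1037000	G	C
ITIH5	c.1063delG	p.D355fs	0	0	0	1	0	NO_CHANGE	0	frameshift_indel	16	1038000	AG	A
PSAT1	c.G511C	p.A171P	0	0	0	1	0	NO_CHANGE	0	nonsynonymous_snv	17	1039000	G	C
URI1	c.G1303T	p.E435X	0	0	0	1	1	NO_CHANGE	0	nonsense	18	1040000	G	T
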