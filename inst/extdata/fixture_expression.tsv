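gene	sample	role	fpkm
ACAP2	T	T	30
ACAP2	N	N	3
ACAP2	C1	C	2.7
ACAP2	C2	C	2.85
ACAP2	C3	C	3
ACAP2	C4	C	3.15
ACAP2	C5	C	3.3
ACTL6A	T	T	19
ACTL6A	N	N	20
ACTL6A	C1	C	18
ACTL6A	C2	C	19
ACTL6A	C3	C	20
ACTL6A	C4	C	21
ACTL6A	C5	C	22
BUB1B	T	T	2
BUB1B	N	N	20
BUB1B	C1	C	18
BUB1B	C2	C	19
BUB1B	C3	C	20
BUB1B	C4	C	21
BUB1B	C5	C	22
DDX11	T	T	19
DDX11	N	N	20
DDX11	C1	C	18
DDX11	C2	C	19
DDX11	C3	C	20
DDX11	C4	C	21
DDX11	C5	C	22
EPB41	T	T	19
EPB41	N	N	20
EPB41	C1	C	18
EPB41	C2	C	19
EPB41	C3	C	20
EPB41	C4	C	21
EPB41	C5	C	22
MEN1	T	T	2
MEN1	N	N	20
MEN1	C1	C	18
MEN1	C2	C	19
MEN1	C3	C	20
MEN1	C4	C	21
MEN1	C5	C	22
ACACA	T	T	2
ACACA	N	N	20
ACACA	C1	C	18
ACACA	C2	C	19
ACACA	C3	C	20
ACACA	C4	C	21
ACACA	C5	C	22
AMIGO3	T	T	1
AMIGO3	N	N	1.2
AMIGO3	C1	C	18
AMIGO3	C2	C	19
AMIGO3	C3	C	20
AMIGO3	C4	C	21
AMIGO3	C5	C	22
AVL9	T	T	19
AVL9	N	N	20
AVL9	C1	C	18
AVL9	C2	C	19
AVL9	C3	C	20
AVL9	C4	C	21
AVL9	C5	C	22
CTBP2	T	T	19
CTBP2	N	N	20
CTBP2	C1	C	18
CTBP2	C2	C	19
CTBP2	C3	C	20
CTBP2	C4	C	21
CTBP2	C5	C	22
CTSZ	T	T	19
CTSZ	N	N	20
CTSZ	C1	C	18
CTSZ	C2	C	19
CTSZ	C3	C	20
CTSZ	C4	C	21
CTSZ	C5	C	22
DEPTOR	T	T	1
DEPTOR	N	N	1.2
DEPTOR	C1	C	18
DEPTOR	C2	C	19
DEPTOR	C3	C	20
DEPTOR	C4	C	21
DEPTOR	C5	C	22
ENO3	T	T	30
ENO3	N	N	3
ENO3	C1	C	2.7
ENO3	C2	C	2.85
ENO3	C3	C	3
ENO3	C4	C	3.15
ENO3	C5	C	3.3
GRM1	T	T	19
GRM1	N	N	20
GRM1	C1	C	18
GRM1	C2	C	19
GRM1	C3	C	20
GRM1	C4	C	21
GRM1	C5	C	22
MYO10	T	T	19
MYO10	N	N	20
MYO10	C1	C	18
MYO10	C2	C	19
MYO10	C3	C	20
MYO10	C4	C	21
MYO10	C5	C	22
PFKP	T	T	19
PFKP	N	N	20
PFKP	C1	C	18
PFKP	C2	C	19
PFKP	C3	C	20
PFKP	C4	C	21
PFKP	C5	C	22
PSCA	T	T	30
PSCA	N	N	3
PSCA	C1	C	2.7
PSCA	C2	C	2.85
PSCA	C3	C	3
PSCA	C4	C	3.15
PSCA	C5	C	3.3
ROCK1	T	T	19
ROCK1	N	N	20
ROCK1	C1	C	18
ROCK1	C2	C	19
ROCK1	C3	C	20
ROCK1	C4	C	21
ROCK1	C5	C	22
WWTR1	T	T	2
WWTR1	N	N	20
WWTR1	C1	C	18
WWTR1	C2	C	19
WWTR1	C3	C	20
WWTR1	C4	C	21
WWTR1	C5	C	22
CARS	T	T	1
CARS	N	N	1.2
CARS	C1	C	18
CARS	C2	C	19
CARS	C3	C	20
CARS	C4	C	21
CARS	C5	C	22
ANGPTL4	T	T	2
ANGPTL4	N	N	20
ANGPTL4	C1	C	18
ANGPTL4	C2	C	19
ANGPTL4	C3	C	20
ANGPTL4	C4	C	21
ANGPTL4	C5	C	22
CUX1	T	T	19
CUX1	N	N	20
CUX1	C1	C	18
CUX1	C2	C	19
CUX1	C3	C	20
CUX1	C4	C	21
CUX1	C5	C	22
EPHB6	T	T	19
EPHB6	N	N	20
EPHB6	C1	C	18
EPHB6	C2	C	19
EPHB6	C3	C	20
EPHB6	C4	C	21
EPHB6	C5	C	22
FBN2	T	T	2
FBN2	N	N	20
FBN2	C1	C	18
FBN2	C2	C	19
FBN2	C3	C	20
FBN2	C4	C	21
FBN2	C5	C	22
GANAB	T	T	19
GANAB	N	N	20
GANAB	C1	C	18
GANAB	C2	C	19
GANAB	C3	C	20
GANAB	C4	C	21
GANAB	C5	C	22
KDM4C	T	T	19
KDM4C	N	N	20
KDM4C	C1	C	18
KDM4C	C2	C	19
KDM4C	C3	C	20
KDM4C	C4	C	21
KDM4C	C5	C	22
MMP14	T	T	2
MMP14	N	N	20
MMP14	C1	C	18
MMP14	C2	C	19
MMP14	C3	C	20
MMP14	C4	C	21
MMP14	C5	C	22
PTPN23	T	T	19
PTPN23	N	N	20
PTPN23	C1	C	18
PTPN23	C2	C	19
PTPN23	C3	C	20
PTPN23	C4	C	21
PTPN23	C5	C	22
RNASEL	T	T	1
RNASEL	N	N	1.2
RNASEL	C1	C	18
RNASEL	C2	C	19
RNASEL	C3	C	20
RNASEL	C4	C	21
RNASEL	C5	C	22
TP73	T	T	2
TP73	N	N	20
TP73	C1	C	18
TP73	C2	C	19
TP73	C3	C	20
TP73	C4	C	21
TP73	C5	C	22
ESRRA	T	T	19
ESRRA	N	N	20
ESRRA	C1	C	18
ESRRA	C2	C	19
ESRRA	C3	C	20
ESRRA	C4	C	21
ESRRA	C5	C	22
ABHD5	T	T	19
ABHD5	N	N	20
ABHD5	C1	C	18
ABHD5	C2	C	19
ABHD5	C3	C	20
ABHD5	C4	C	21
ABHD5	C5	C	22
ACAD9	T	T	19
ACAD9	N	N	20
ACAD9	C1	C	18
ACAD9	C2	C	19
ACAD9	C3	C	20
ACAD9	C4	C	21
ACAD9	C5	C	22
EPHA7	T	T	19
EPHA7	N	N	20
EPHA7	C1	C	18
EPHA7	C2	C	19
EPHA7	C3	C	20
EPHA7	C4	C	21
EPHA7	C5	C	22
EPN3	T	T	19
EPN3	N	N	20
EPN3	C1	C	18
EPN3	C2	C	19
EPN3	C3	C	20
EPN3	C4	C	21
EPN3	C5	C	22
IQGAP2	T	T	1
IQGAP2	N	N	1.2
IQGAP2	C1	C	18
IQGAP2	C2	C	19
IQGAP2	C3	C	20
IQGAP2	C4	C	21
IQGAP2	C5	C	22
ITIH5	T	T	19
ITIH5	N	N	20
ITIH5	C1	C	18
ITIH5	C2	C	19
ITIH5	C3	C	20
ITIH5	C4	C	21
ITIH5	C5	C	22
PSAT1	T	T	19
PSAT1	N	N	20
PSAT1	C1	C	18
PSAT1	C2	C	19
PSAT1	C3	C	20
PSAT1	C4	C	21
PSAT1	C5	C	22
URI1	T	T	19
URI1	N	N	20
URI1	C1	C	18
URI1	C2	C	19
URI1	C3	C	20
URI1	C4	C	21
URI1	C5	C	22
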