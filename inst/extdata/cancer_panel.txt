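# Cancer-predisposition gene panel used by the packaged worked example:
# genes previously associated with cancer of the lung or other tissues.
ABHD5
ACACA
ACAD9
ACAP2
ACTL6A
AMIGO3
ANGPTL4
AVL9
BUB1B
CARS
CTBP2
CTSZ
CUX1
DDX11
DEPTOR
ENO3
EPB41
EPHA7
EPHB6
EPN3
ESRRA
FBN2
GANAB
GRM1
IQGAP2
ITIH5
KDM4C
MEN1
MMP14
MYO10
PFKP
PSAT1
PSCA
PTPN23
RNASEL
ROCK1
TP73
URI1
WWTR1
AKT1
ALK
BRCA1
BRCA2
EGFR
KRAS
MET
RAD51
STK11
TP53
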