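gene1	gene2	sign	pmids
CLOCK	PER1	activation	900001
CLOCK	PER2	activation	900001
CLOCK	PER3	activation	900001
CLOCK	CRY1	activation	900001
CLOCK	CRY2	activation	900001
CLOCK	NR1D1	activation	900001
CLOCK	NR1D2	activation	900001
CLOCK	RORA	activation	900001
CLOCK	RORC	activation	900001
CLOCK	DBP	activation	900001
CLOCK	BHLHE40	activation	900001
CLOCK	BHLHE41	activation	900001
CLOCK	TEF	activation	900001
CLOCK	HLF	activation	900001
ARNTL	PER1	activation	900001
ARNTL	PER2	activation	900001
ARNTL	PER3	activation	900001
ARNTL	CRY1	activation	900001
ARNTL	CRY2	activation	900001
ARNTL	NR1D1	activation	900001
ARNTL	NR1D2	activation	900001
ARNTL	RORA	activation	900001
ARNTL	RORC	activation	900001
ARNTL	DBP	activation	900001
ARNTL	BHLHE40	activation	900001
ARNTL	BHLHE41	activation	900001
ARNTL	TEF	activation	900001
ARNTL	HLF	activation	900001
NPAS2	PER1	activation	900002
NPAS2	PER2	activation	900002
NPAS2	CRY1	activation	900002
NPAS2	NR1D1	activation	900002
CLOCK	PER2	activation	900003
ARNTL2	PER2	activation	900003
PER1	CLOCK	inhibition	900004
PER1	ARNTL	inhibition	900004
PER2	CLOCK	inhibition	900004
PER2	ARNTL	inhibition	900004
PER3	CLOCK	inhibition	900004
PER3	ARNTL	inhibition	900004
CRY1	CLOCK	inhibition	900004
CRY1	ARNTL	inhibition	900004
CRY2	CLOCK	inhibition	900004
CRY2	ARNTL	inhibition	900004
NR1D1	ARNTL	inhibition	900005
NR1D1	ARNTL2	inhibition	900005
NR1D1	CLOCK	inhibition	900005
NR1D1	NFIL3	inhibition	900005
NR1D2	ARNTL	inhibition	900005
NR1D2	ARNTL2	inhibition	900005
NR1D2	CLOCK	inhibition	900005
NR1D2	NFIL3	inhibition	900005
RORA	ARNTL	activation	900006
RORA	ARNTL2	activation	900006
RORA	NFIL3	activation	900006
RORB	ARNTL	activation	900006
RORB	ARNTL2	activation	900006
RORB	NFIL3	activation	900006
RORC	ARNTL	activation	900006
RORC	ARNTL2	activation	900006
RORC	NFIL3	activation	900006
CSNK1D	PER1	other	900007
CSNK1D	PER2	other	900007
CSNK1D	PER3	other	900007
CSNK1E	PER1	other	900007
CSNK1E	PER2	other	900007
CSNK1E	PER3	other	900007
CSNK2A1	PER2	other	900008
GSK3B	PER2	other	900008
GSK3B	CRY2	other	900008
GSK3B	NR1D1	other	900008
FBXL3	CRY1	inhibition	900009
FBXL3	CRY2	inhibition	900009
FBXL21	CRY1	inhibition	900009
FBXL21	CRY2	inhibition	900009
BTRC	PER1	inhibition	900010
BTRC	PER2	inhibition	900010
SIRT1	ARNTL	other	900011
SIRT1	PER2	inhibition	900011
EP300	ARNTL	activation	900012
CREBBP	ARNTL	activation	900012
CREB1	PER1	activation	900013
CREB1	PER2	activation	900013
PRKAA1	CRY1	inhibition	900014
PRKAA2	CRY1	inhibition	900014
NONO	PER1	other	900015
PSPC1	PER1	other	900015
SFPQ	PER1	other	900015
WDR5	PER1	other	900016
PARP1	CLOCK	other	900017
DBP	PER1	activation	900018
NFIL3	PER1	inhibition	900018
TEF	PER1	activation	900018
HLF	PER1	activation	900018
BHLHE40	CLOCK	inhibition	900019
BHLHE41	CLOCK	inhibition	900019
TIMELESS	CRY1	other	900020
CIART	ARNTL	inhibition	900021
ID2	CLOCK	inhibition	900022
MYBBP1A	PER2	other	900023
PML	PER2	other	900024
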