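gene	layer
PER1	CCN
PER2	CCN
PER3	CCN
CRY1	CCN
CRY2	CCN
ARNTL	CCN
ARNTL2	CCN
CLOCK	CCN
NPAS2	CCN
NR1D1	CCN
NR1D2	CCN
RORA	CCN
RORB	CCN
RORC	CCN
CSNK1D	ECCN
CSNK1E	ECCN
CSNK2A1	ECCN
GSK3B	ECCN
FBXL3	ECCN
FBXL21	ECCN
BTRC	ECCN
SIRT1	ECCN
EP300	ECCN
CREBBP	ECCN
CREB1	ECCN
PRKAA1	ECCN
PRKAA2	ECCN
NONO	ECCN
WDR5	ECCN
PARP1	ECCN
BHLHE40	ECCN
BHLHE41	ECCN
DBP	ECCN
TEF	ECCN
HLF	ECCN
NFIL3	ECCN
TIMELESS	ECCN
CIART	ECCN
ID2	ECCN
PSPC1	ECCN
SFPQ	ECCN
MYBBP1A	ECCN
PML	ECCN
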