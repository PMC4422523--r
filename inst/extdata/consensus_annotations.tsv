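entrezID	symbol	reverb_a	reverb_b	reverb_ab	ror_a	ror_g	ror_ag	circadian	high_A	long_T	short_T	bmal1	omim
102	ADAM10		x										Reticulate acropigmentation of Kitamura, 615537 (3); {Alzheimer disease 18, susceptibility to}, 615590 (3)
328	APEX1	x											
350	APOH	x	x	x	x	x	x	x					
466	ATF1			x									
471	ATIC	x										x	AICA-ribosiduria due to ATIC deficiency, 608688 (3)
551	AVP							x					Diabetes insipidus, neurohypophyseal, 125700 (3)
813	CALU		x		x								
885	CCK	x											
996	CDC27			x									
1108	CHD4			x				x					
1195	CLK1							x					3MC syndrome 2, 265050 (3)
1386	ATF2												
1452	CSNK1A1	x	x	x						x			
1459	CSNK2A2			x									
1499	CTNNB1	x		x									Colorectal cancer, somatic, 114500 (3); Hepatocellular carcinoma, somatic, 114550 (3); Mental retardation, autosomal dominant 19, 615075 (3); Ovarian cancer, somatic, 167000 (3); Pilomatricoma, somatic, 132600 (3)
1642	DDB1			x					x			x	
1656	DDX6			x				x					
1660	DHX9							x					
1855	DVL1			x									
1859	DYRK1A	x	x	x									Mental retardation, autosomal dominant 7, 614104 (3)
1915	EEF1A1	x	x		x								
1994	ELAVL1												
2177	FANCD2			x									Fanconi anemia, complementation group D2, 227646 (3)
2547	XRCC6	x											
2875	GPT	x	x	x									
2905	GRIN2C	x	x	x									
3308	HSPA4					x							
3454	IFNAR1		x	x		x		x					
4089	SMAD4	x						x					Juvenile polyposis/hereditary hemorrhagic telangiectasia syndrome, 175050 (3); Myhre syndrome, 139210 (3); Pancreatic cancer, somatic, 260350 (3); Polyposis, juvenile intestinal, 174900 (3)
4297	MLL	x	x	x									Leukemia, myeloid/lymphoid or mixed-lineage (2); Wiedemann-Steiner syndrome, 605130 (3)
4299	AFF1	x	x	x									
4670	HNRNPM							x					
4691	NCL				x			x		x			
4830	NME1	x		x									Neuroblastoma, 256700 (3)
4836	NMT1	x	x					x					
5430	POLR2A				x								
5469	MED1			x		x							
5478	PPIA			x									
5599	MAPK8	x		x						x			
5663	PSEN1				x			x					Acne inversa, familial, 3, 613737 (3); Alzheimer disease, type 3, 607822 (3); Alzheimer disease, type 3, with spastic paraparesis and apraxia, 607822 (3); Alzheimer disease, type 3, with spastic paraparesis and unusual plaques, 607822 (3); Cardiomyopathy, dilated, 1U, 613694 (3); Dementia, frontotemporal, 600274 (3); Pick disease, 172700 (3)
5725	PTBP1	x		x									
5931	RBBP7												
5980	REV3L			x									
6125	RPL5			x									Diamond-Blackfan anemia 6, 612561 (3)
6667	SP1	x		x		x							
6868	ADAM17							x					Inflammatory skin and bowel disease, neonatal, 614328 (3)
7248	TSC1	x		x									Focal cortical dysplasia, Taylor balloon cell type, 607341 (3); Lymphangioleiomyomatosis, 606690 (3); Tuberous sclerosis-1, 191100 (3)
7341	SUMO1							x					Orofacial cleft 10, 613705 (3)
7520	XRCC5		x										
7994	KAT6A	x		x									
8021	NUP214			x									Leukemia, T-cell acute lymphoblastic (3); Leukemia, acute myeloid, 601626 (3)
8202	NCOA3	x	x	x									
8491	MAP4K3	x	x					x					
8615	USO1	x	x	x									
8648	NCOA1							x					
9318	COPS2										x		
9611	NCOR1	x	x	x									
9612	NCOR2	x	x	x									
10059	DNM1L							x					Encephalopahty, lethal, due to defective mitochondrial peroxisomal fission, 614388 (3)
10432	RBM14		x	x	x	x	x						
10499	NCOA2	x											
10615	SPAG5		x		x	x	x						
10664	CTCF			x									Mental retardation, autosomal dominant 21, 615502 (3)
10725	NFAT5			x									
10728	PTGES3			x				x					
11331	PHB2							x					
23013	SPEN	x		x									Megakaryoblastic leukemia, acute (2)
26959	HBP1	x											
27113	BBC3	x		x									
27327	TNRC6A		x										
28996	HIPK2	x	x										
51514	DTL	x	x	x									
54464	XRN1			x									
55031	USP47		x	x									
57786	RBAK				x								
79664	NARG2	x	x	x	x								
90480	GADD45GIP1			x									
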