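term	ontology	annotated	significant	expected	fdr
nuclear mRNA splicing, via spliceosome	BP	200	88	27	1.9e-10
cell division	BP	443	114	59.81	1.6e-09
mRNA transport	BP	105	54	14.18	6.7e-08
DNA strand elongation involved in DNA replication	BP	34	21	4.59	1.2e-06
ubiquitin-dependent protein catabolic process	BP	347	104	46.85	1.7e-06
S phase of mitotic cell cycle	BP	130	44	17.55	1.8e-06
regulation of glucose transport	BP	69	24	9.32	1.9e-06
mitotic prometaphase	BP	84	35	11.34	1.9e-06
M/G1 transition of mitotic cell cycle	BP	76	32	10.26	8.4e-06
mRNA processing	BP	378	152	51.03	1.9e-05
gene expression	BP	4347	874	586.86	0.00027
cell cycle checkpoint	BP	234	70	31.59	0.00031
DNA duplex unwinding	BP	28	18	3.78	0.00033
nuclear-transcribed mRNA poly(A) tail shortening	BP	26	16	3.51	0.00038
mRNA export from nucleus	BP	59	28	7.97	0.00042
protein transport	BP	1154	222	155.79	0.00047
DNA-dependent DNA replication initiation	BP	28	16	3.78	0.00079
DNA repair	BP	369	109	49.82	0.00120
termination of RNA polymerase II transcription	BP	44	20	5.94	0.00285
regulation of transcription, DNA-templated	BP	2735	506	369.23	0.00518
RNA splicing	BP	308	121	41.58	0.00989
protein binding	MF	6831	1116	889.85	2.6e-29
RNA binding	MF	792	248	103.17	7.0e-24
DNA binding	MF	2240	454	291.8	5.8e-14
ATP binding	MF	1439	292	187.45	9.4e-13
nucleotide binding	MF	2294	448	298.83	3.3e-07
ubiquitin thiolesterase activity	MF	64	27	8.34	2.6e-05
chromatin binding	MF	235	59	30.61	0.00026
ubiquitin-protein ligase activity	MF	241	63	31.39	0.00104
translation initiation factor activity	MF	50	21	6.51	0.00134
ubiquitin-specific protease activity	MF	43	19	5.6	0.00186
ATP-dependent DNA helicase activity	MF	32	17	4.17	0.00547
protein transporter activity	MF	87	28	11.33	0.00865
nucleus	CC	5640	1172	724.54	2.1e-30
nucleoplasm	CC	1401	423	179.98	1.0e-27
nuclear speck	CC	144	61	18.5	1.3e-15
nucleolus	CC	589	154	75.67	2.4e-14
catalytic step 2 spliceosome	CC	78	40	10.02	3.7e-13
nuclear pore	CC	60	36	7.71	5.6e-10
cytosol	CC	2217	382	284.8	3.6e-07
heterogeneous nuclear ribonucleoprotein complex	CC	19	14	2.44	2.5e-06
centrosome	CC	363	89	46.63	3.9e-05
Cajal body	CC	44	20	5.65	0.00014
cytoplasmic stress granule	CC	21	12	2.7	0.00239
spliceosomal complex	CC	137	60	17.6	0.00322
nuclear pore outer ring	CC	10	8	1.28	0.00330
chromatin	CC	280	72	35.97	0.00466
DNA replication factor C complex	CC	6	6	0.77	0.00568
chaperonin-containing T-complex	CC	6	6	0.77	0.00568
nuclear membrane	CC	169	46	21.71	0.00685
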