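family_id	name	size	swissprot_count	pcid_avg	pcid_std	n_euk	n_bact	n_arch
MDR001	ADH	2217	116	51.24	19.02	1315	895	6
MDR002	PTGR	774	17	42.46	9.64	253	518	3
MDR003	FAS	706	11	39.07	9.88	288	418	0
MDR004	QORX	486	1	47.47	10.07	69	417	0
MDR005	PDH	328	18	45.59	11.81	181	146	1
MDR006	ZADH2	56	4	51.49	15.19	51	5	0
MDR007	MECR	51	9	54.6	13.15	51	0	0
MDR008	VAT1	50	6	60.49	19.6	48	2	0
MDR009	vertQOR	22	8	70.12	10.34	21	1	0
MDR010	CAD	661	32	49.08	10.02	329	330	2
MDR011	bpQOR	575	5	47.93	11.86	66	509	0
MDR012	YHDH	481	2	53.92	11.43	1	477	0
MDR013	FDH	375	4	47.16	12.56	29	346	0
MDR014	TDH	351	126	69.4	16.11	1	343	7
MDR015	QORL2	319	4	45.25	8.76	38	281	0
MDR016	bADH	313	17	60.72	15.62	1	312	0
MDR017		279	8	51.97	8.93	2	277	0
MDR018		194	1	47.22	10.6	48	146	0
MDR019		136	0	60.51	12.37	18	118	0
MDR020	yADH	128	22	63.56	12.11	128	0	0
MDR021	YJGB	122	1	69.98	20.96	2	120	0
MDR022	giFDH	122	2	63.32	18.53	5	111	6
MDR023		72	5	52.93	17.12	10	56	6
MDR024		40	0	52.66	11.72	7	32	1
MDR025	yPDH	34	0	65.44	13.11	34	0	0
MDR026	yDH	34	0	60.48	13.13	34	0	0
MDR027	QORH	34	2	60.28	10.85	34	0	0
MDR028		29	0	55.36	9.11	1	28	0
MDR029	yADH2	29	1	59.02	15.24	29	0	0
MDR030	dFAS	28	0	57.51	16.34	28	0	0
MDR031	yDH2	28	0	53.43	12.87	28	0	0
MDR032	bADH2	26	0	69.59	17.08	1	25	0
MDR033	yBDH	23	2	54.51	12.62	23	0	0
MDR034		23	0	54.57	14.09	13	10	0
MDR035		22	0	47.17	10.55	22	0	0
MDR036	bADH3	21	4	50.26	15.82	1	12	8
MDR037		20	0	66.14	13.09	20	0	0
MDR038		20	0	74.56	12.47	20	0	0
MDR039	bADH4	150	0	58.99	10.83	0	150	0
MDR040	SORE	117	2	61.62	21.91	0	117	0
MDR041	BurkDH	114	0	63.89	15.74	0	114	0
MDR042	YJJN	114	1	57.5	18.31	0	114	0
MDR043	IDND	96	1	55.99	17.9	0	96	0
MDR044		96	0	54.24	13.62	0	92	4
MDR045		89	0	56.57	14.09	0	89	0
MDR046	RSPB	78	1	72.88	16.8	0	78	0
MDR047		72	0	58.49	18.18	0	72	0
MDR048	GATD	71	2	83.33	14.94	0	71	0
MDR049		69	0	54.89	14.55	0	69	0
MDR050	CCR	67	0	72.88	15.83	0	67	0
MDR051	TARJ	63	1	60.87	21.7	0	62	1
MDR052	YCJQ	48	2	91.08	10.57	0	48	0
MDR053		48	0	50.84	14.22	0	48	0
MDR054	YDJL	46	1	93.7	12.44	0	46	0
MDR055		44	0	63.84	10.29	0	44	0
MDR056		44	0	63.41	20.64	0	44	0
MDR057	BCHC	43	2	61.89	8.07	0	43	0
MDR058		43	0	76.53	11.52	0	43	0
MDR059		42	0	56.97	9.37	0	42	0
MDR060	YPHC	42	1	84.08	22.01	0	42	0
MDR061	bBDH	40	0	63.33	22.56	0	40	0
MDR062	CCR2	40	0	73.01	14.76	0	40	0
MDR063		38	0	58.21	20.04	0	38	0
MDR064		33	0	81.63	18.31	0	33	0
MDR065		32	0	53.79	11.72	0	31	1
MDR066		32	1	82.45	18.25	0	32	0
MDR067	bQOR	32	0	73.92	21.12	0	32	0
MDR068		32	0	55.05	10.93	0	32	0
MDR069		32	0	54.76	13.41	0	30	2
MDR070		31	0	50.14	19.08	0	31	0
MDR071		31	0	52.17	11.37	0	31	0
MDR072	bDHSO	31	1	65.28	20.13	0	31	0
MDR073	bQOR2	31	0	81.84	19.4	0	31	0
MDR074		30	0	79.07	19.18	0	30	0
MDR075		29	0	82.92	18.37	0	29	0
MDR076		29	0	57.41	13.46	0	29	0
MDR077		28	0	58.92	10.41	0	24	4
MDR078	RhobDH	25	0	55.27	11.23	0	25	0
MDR079		25	0	63.69	12.82	0	25	0
MDR080	bPDH	24	0	75.24	15.12	0	24	0
MDR081		23	0	53.96	19.57	0	23	0
MDR082		23	0	63.98	10.48	0	23	0
MDR083		21	0	57.76	20.4	0	9	12
MDR084		21	0	44.68	12.83	0	21	0
MDR085		21	0	68.74	15.71	0	21	0
MDR086	MycDH	20	0	65.99	28.08	0	20	0
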