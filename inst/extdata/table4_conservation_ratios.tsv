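family_id	name	catalytic	coenzyme	ratio
MDR005	PDH	28	8	3.5
MDR080	bPDH	97	32	3.03
MDR070		30	10	3
MDR013	FDH	39	13	3
MDR047		47	20	2.35
MDR075		65	28	2.32
MDR032	bADH2	60	27	2.22
MDR065		41	19	2.16
MDR076		43	20	2.15
MDR004	QORX	17	8	2.13
MDR002	PTGR	7	14	0.5
MDR035		12	27	0.44
MDR003	FAS	8	18	0.44
MDR008	VAT1	10	37	0.27
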