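gene_id	protein	expression_ratio	mutant_id	growth_ratio	significant	models	previously_reported
AT4G14400	Accelerated cell death 6 (ACD6)	0.06	SALK_059132	1.73	TRUE	LR	TRUE
AT4G14400	Accelerated cell death 6 (ACD6)	0.06	SALK_116079	1.46	TRUE	LR	TRUE
AT5G02360	Domain C1 containing protein	0.09	SALK_004531	1.75	TRUE	LR	FALSE
AT5G02360	Domain C1 containing protein	0.09	SALK_004524	2.46	TRUE	LR	FALSE
AT2G18260	AtSYP112	0.14	SALK_037621	2.47	TRUE	EMMAX+LR	FALSE
AT2G18260	AtSYP112	0.14	CS26712	2.21	TRUE	EMMAX+LR	FALSE
AT2G18260	AtSYP112	0.14	CS868715	1.87	TRUE	EMMAX+LR	FALSE
AT1G61310	NB-ARC LRR	0.43	SALK_125189	2.66	TRUE	EMMAX+LR	FALSE
AT1G61310	NB-ARC LRR	0.43	SALK_029306	1.56	TRUE	EMMAX+LR	FALSE
AT2G19110	Heavy metal ATPase 4	0.5	SALK_042898	2.1	TRUE	EMMAX	FALSE
AT2G19110	Heavy metal ATPase 4	0.5	SALK_093482	3.65	TRUE	EMMAX	FALSE
AT5G41750	TIR-NB-LRR	0.53	SALK_066101	1.34	TRUE	EMMAX+LR	FALSE
AT5G41750	TIR-NB-LRR	0.53	SALK_085020	1.64	TRUE	EMMAX+LR	FALSE
AT5G23420	High-mobility group box 6	0.62	SALK_138632	2.12	TRUE	LR	FALSE
AT5G23420	High-mobility group box 6	0.62	SALK_044693	1.56	TRUE	LR	FALSE
AT5G52460	F-box leucine-rich repeat protein	0.71	SALK_013776	2.77	TRUE	EMMAX	FALSE
AT5G52460	F-box leucine-rich repeat protein	0.71	SALK_031583	0.39	TRUE	EMMAX	FALSE
AT3G61600	LRB2; POZ/BTB containing G-protein 1	0.76	SALK_100118	2.36	TRUE	LR	FALSE
AT3G61600	LRB2; POZ/BTB containing G-protein 1	0.76	SALK_128387	2.78	TRUE	LR	FALSE
AT3G24900	Receptor-like protein 39	1.31	CS868997	0.74	TRUE	EMMAX	FALSE
AT3G24900	Receptor-like protein 39	1.31	SALK_126504	0.6	TRUE	EMMAX	FALSE
AT1G31870	Bud site-selection protein 13	1.52	SALK_018219	1.77	TRUE	EMMAX+LR	FALSE
AT1G31870	Bud site-selection protein 13	1.52	SALK_096851	1.58	TRUE	EMMAX+LR	FALSE
AT2G19060	SGNH hydrolase-type esterase	1.68	SALK_061864	2.47	TRUE	EMMAX+LR	FALSE
AT2G19060	SGNH hydrolase-type esterase	1.68	SALK_117794	1.72	TRUE	EMMAX+LR	FALSE
AT2G19060	SGNH hydrolase-type esterase	1.68	SALK_115819	1.86	TRUE	EMMAX+LR	FALSE
AT2G04300	Leucine-rich repeat protein kinase	4.37	SALK_003316	2.3	TRUE	EMMAX+LR	FALSE
AT2G04300	Leucine-rich repeat protein kinase	4.37	SALK_003328	1.85	TRUE	EMMAX+LR	FALSE
AT4G12040	Stress-associated protein 7	5.97	SALK_071408	-1.03	TRUE	LR	FALSE
AT4G12040	Stress-associated protein 7	5.97	SALK_071504	0.58	TRUE	LR	FALSE
AT4G12000	SNARE associated Golgi protein	10.37	SALK_021373	0.51	TRUE	EMMAX	FALSE
AT4G12000	SNARE associated Golgi protein	10.37	SALK_204172	0.67	TRUE	EMMAX	FALSE
AT2G31360	16:0 delta 9 desaturase 2	26.04	SALK_079963	0.05	TRUE	EMMAX	TRUE
AT2G31360	16:0 delta 9 desaturase 2	26.04	SALK_016783	-0.49	TRUE	EMMAX	TRUE
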