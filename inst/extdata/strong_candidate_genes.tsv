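gene_id	protein	expression_ratio	mutant_id	growth_ratio	significant	models	previously_reported
AT3G61480	Quinoprotein amine dehydrogenase	0.84	SALK_017426	1.49	TRUE	LR	FALSE
AT3G61480	Quinoprotein amine dehydrogenase	0.84	SALK_099827	0.96	FALSE	LR	FALSE
AT1G31640	Agamous-like 92	0.85	SALK_030847C	1.79	TRUE	EMMAX	FALSE
AT1G31640	Agamous-like 92	0.85	SALK_035114C	1.17	FALSE	EMMAX	FALSE
AT2G27120	DNA polymerase epsilon catalytic subunit	0.92	SALK_025607	2.52	TRUE	LR	FALSE
AT2G27120	DNA polymerase epsilon catalytic subunit	0.92	SALK_056503	0.81	FALSE	LR	FALSE
AT3G53520	UDP-glucuronic acid decarboxylase 1	1.07	SALK_068865	1.36	TRUE	EMMAX+LR	FALSE
AT3G53520	UDP-glucuronic acid decarboxylase 1	1.07	SALK_152673	1.25	FALSE	EMMAX+LR	FALSE
AT2G39840	Type 1 phosphoprotein Ser/Thr phosphatase	1.34	SALK_090980	0.97	FALSE	EMMAX+LR	FALSE
AT2G39840	Type 1 phosphoprotein Ser/Thr phosphatase	1.34	SALK_090981	1.22	FALSE	EMMAX+LR	FALSE
AT2G39840	Type 1 phosphoprotein Ser/Thr phosphatase	1.34	CS375515	-0.73	TRUE	EMMAX+LR	FALSE
AT4G12350	AtMYB42	1.37	SALK_003422	1.28	TRUE	EMMAX	FALSE
AT4G12350	AtMYB42	1.37	SALK_032016	0.86	FALSE	EMMAX	FALSE
AT5G54960	Pyruvate decarboxylase-2	2.43	SALK_053107	0.48	TRUE	EMMAX	FALSE
AT3G43148	Myosin heavy chain-like protein	NA	SALK_151592	0.55	TRUE	EMMAX	FALSE
AT3G43148	Myosin heavy chain-like protein	NA	SALK_076725	0.96	FALSE	EMMAX	FALSE
AT5G39500	Endoplasmic reticulum morphology 1	NA	SALK_020371	0.57	TRUE	EMMAX	FALSE
AT5G39500	Endoplasmic reticulum morphology 1	NA	SALK_091078	1.21	FALSE	EMMAX	FALSE
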