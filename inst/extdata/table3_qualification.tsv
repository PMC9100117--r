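uniprot_id	protein	gene	cp_ratio	q_control	q_diff_115v114	q_diff_115v116
P11217	Glycogen phosphorylase, muscle isoform	PYGM	4.527	0.23	5.99e-11	5.99e-11
P20929-2	Nebulin	NEB	1.597	0.25	7.31e-07	1.97e-07
Q14324	Myosin-binding protein C, fast-type	MYBPC2	2.035	0.22	3.39e-05	5.50e-06
P14618-2	Pyruvate kinase, isoform 1	PKM	1.379	0.03	1.58e-08	1.01e-10
P08237	ATP-dependent 6-phosphofructokinase, muscle type	PFKM	1.521	0.26	8.77e-05	8.77e-05
P04075	Fructose-bisphosphate aldolase A	ALDOA	1.626	0.02	2.80e-06	5.35e-07
Q8WZ42-11	Titin, isoform 11	TTN	1.492	0.05	1.01e-10	1.48e-11
Q08043	Alpha-actinin-3	ACTN3	2.265	0.26	1.91e-07	2.92e-08
P00558-2	Phosphoglycerate kinase 1, isoform 2	PGK1	1.578	0.04	3.39e-05	3.39e-05
O14983-2	Sarcoplasmic/endoplasmic reticulum calcium ATPase 1, isoform SERCA1A	ATP2A1	1.680	0.26	2.66e-05	4.24e-06
O60662	Kelch-like protein 41	KLHL41	1.469	0.26	2.12e-05	2.12e-05
P54296	Myomesin-2	MYOM2	1.465	0.45	2.12e-05	2.12e-05
P13929	Beta-enolase	ENO3	1.542	0.03	3.39e-05	5.50e-06
P16615-2	Sarcoplasmic/endoplasmic reticulum calcium ATPase 2, isoform 2	ATP2A2	1.363	0.24	7.75e-03	1.74e-03
P12882	Myosin-1	MYH1	1.972	0.04	8.49e-10	1.46e-10
P04406-2	Glyceraldehyde-3-phosphate dehydrogenase, isoform 2	GAPDH	1.422	0.04	2.29e-04	2.29e-04
P06576	ATP synthase subunit beta, mitochondrial	ATP5F1B	1.157	0.13	1.63e-02	2.69e-03
P25705	ATP synthase subunit alpha, mitochondrial	ATP5F1A	1.142	0.07	1.34e-02	1.05e-02
P17661	Desmin	DES	1.200	0.14	1.54e-03	2.83e-05
P06732	Creatine kinase M-type	CKM	1.517	0.05	6.43e-09	1.12e-09
Q14315-2	Filamin-C, isoform 2	FLNC	1.253	0.05	5.83e-05	1.20e-05
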