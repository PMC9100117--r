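uniprot_id	ch_115	ch_114	ch_116	cp_ratio	swissprot_id	protein	gene
P11217	0.924	4.056	4.315	4.527	P11217	Glycogen phosphorylase, muscle isoform	PYGM
H9KVA2	0.916	1.979	2.233	2.298	P45378	Troponin T, fast skeletal muscle	TNNT3
C9JZN9	1.079	2.263	2.668	2.286	P45378	Troponin T, fast skeletal muscle	TNNT3
Q08043	0.933	2.002	2.224	2.265	Q08043	Alpha-actinin-3	ACTN3
P09493	0.987	1.955	2.265	2.137	P09493	Tropomyosin alpha-1 chain	TPM1
Q13642-1	1.050	1.942	2.408	2.072	Q13642	Four and a half LIM domains protein 1, isoform 1	FHL1
Q14324	0.979	1.790	2.196	2.035	Q14324	Myosin-binding protein C, fast-type	MYBPC2
P12882	1.018	1.863	2.151	1.972	P12882	Myosin-1	MYH1
Q13643	1.150	1.992	2.410	1.913	Q13643	Four and a half LIM domains protein 3	FHL3
Q9NR12-6	1.027	1.844	1.919	1.832	Q9NR12	PDZ and LIM domain protein 7, isoform 6	PDLIM7
Q96A32	1.078	1.712	2.079	1.759	Q96A32	Myosin regulatory light chain 2, skeletal muscle isoform	MYLPF
P15121	0.910	1.473	1.676	1.731	P15121	Aldose reductase	AKR1B1
A0A087WXS0	0.961	1.686	1.614	1.718	P48788	Troponin I, fast skeletal muscle	TNNI2
Q96DG6	0.942	1.606	1.592	1.697	Q96DG6	Carboxymethylenebutenolidase homolog	CMBL
O14983-2	1.030	1.758	1.705	1.680	O14983	Sarcoplasmic/endoplasmic reticulum calcium ATPase 1, isoform SERCA1A	ATP2A1
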