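gene	uniprot_id	score	category	effector_motifs	interactors
MYH1	P12882	93	very_strong	elevated cytosolic calcium levels;persistent contraction of muscle cell
ATP2A1	O14983	93	very_strong	elevated cytosolic calcium levels
TPM1	P09493	92	very_strong	elevated cytosolic calcium levels;persistent contraction of muscle cell	MYH11;MYH6;MYH8;MYL1;MYL6;TNNC1;TNNI1;TNNI2;TNNT1;TNNT3;TPM2;TPM3;TPM4
TNNI2	P48788	85	strong	elevated cytosolic calcium levels;persistent contraction of muscle cell	MYH6;MYH8;MYL1;TNNC1;TNNI1;TNNT1;TNNT3;TPM1;TPM2;TPM3;TPM4
TNNT3	P45378	83	strong	elevated cytosolic calcium levels;persistent contraction of muscle cell	MYH6;MYH8;MYL1;TNNC1;TNNI1;TNNI2;TNNT1;TPM1;TPM2;TPM3;TPM4
PYGM	P11217	75	medium_strong	glycogenolysis blockade	GBE1;GYS1;PHKA1;TPM2
PDLIM7	Q9NR12	66	medium_strong		TPM2
ACTN3	Q08043	43	medium_strong		MYH6;MYH8;MYL1;TNNC1;TNNI1;TNNI2;TNNT1;TNNT3;TPM1;TPM2;TPM3;TPM4
MYBPC2	Q14324	38	weak		MYH6;MYH8;MYL1;TNNC1;TNNI1;TNNI2;TNNT1;TNNT3;TPM1;TPM2;TPM3;TPM4
FHL3	Q13643	36	weak
FHL1	Q13642	27	weak
MYLPF	Q96A32	18	weak		MYH11;MYL6;MYLK2;SLC2A4;TPM1;TPM2;TPM3;TPM4
AKR1B1	P15121	17	weak
CMBL	Q96DG6	10	weak
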