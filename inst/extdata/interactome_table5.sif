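MYH1
ATP2A1
TPM1	pp	MYH11
TPM1	pp	MYH6
TPM1	pp	MYH8
TPM1	pp	MYL1
TPM1	pp	MYL6
TPM1	pp	TNNC1
TPM1	pp	TNNI1
TPM1	pp	TNNI2
TPM1	pp	TNNT1
TPM1	pp	TNNT3
TPM1	pp	TPM2
TPM1	pp	TPM3
TPM1	pp	TPM4
TNNI2	pp	MYH6
TNNI2	pp	MYH8
TNNI2	pp	MYL1
TNNI2	pp	TNNC1
TNNI2	pp	TNNI1
TNNI2	pp	TNNT1
TNNI2	pp	TNNT3
TNNI2	pp	TPM1
TNNI2	pp	TPM2
TNNI2	pp	TPM3
TNNI2	pp	TPM4
TNNT3	pp	MYH6
TNNT3	pp	MYH8
TNNT3	pp	MYL1
TNNT3	pp	TNNC1
TNNT3	pp	TNNI1
TNNT3	pp	TNNI2
TNNT3	pp	TNNT1
TNNT3	pp	TPM1
TNNT3	pp	TPM2
TNNT3	pp	TPM3
TNNT3	pp	TPM4
PYGM	pp	GBE1
PYGM	pp	GYS1
PYGM	pp	PHKA1
PYGM	pp	TPM2
PDLIM7	pp	TPM2
ACTN3	pp	MYH6
ACTN3	pp	MYH8
ACTN3	pp	MYL1
ACTN3	pp	TNNC1
ACTN3	pp	TNNI1
ACTN3	pp	TNNI2
ACTN3	pp	TNNT1
ACTN3	pp	TNNT3
ACTN3	pp	TPM1
ACTN3	pp	TPM2
ACTN3	pp	TPM3
ACTN3	pp	TPM4
MYBPC2	pp	MYH6
MYBPC2	pp	MYH8
MYBPC2	pp	MYL1
MYBPC2	pp	TNNC1
MYBPC2	pp	TNNI1
MYBPC2	pp	TNNI2
MYBPC2	pp	TNNT1
MYBPC2	pp	TNNT3
MYBPC2	pp	TPM1
MYBPC2	pp	TPM2
MYBPC2	pp	TPM3
MYBPC2	pp	TPM4
FHL3
FHL1
MYLPF	pp	MYH11
MYLPF	pp	MYL6
MYLPF	pp	MYLK2
MYLPF	pp	SLC2A4
MYLPF	pp	TPM1
MYLPF	pp	TPM2
MYLPF	pp	TPM3
MYLPF	pp	TPM4
AKR1B1
CMBL
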