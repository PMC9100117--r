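motif	gene
elevated cytosolic calcium levels	MYH1
elevated cytosolic calcium levels	ATP2A1
elevated cytosolic calcium levels	TPM1
elevated cytosolic calcium levels	TNNI2
elevated cytosolic calcium levels	TNNT3
elevated cytosolic calcium levels	MYH11
elevated cytosolic calcium levels	MYH6
elevated cytosolic calcium levels	MYH8
elevated cytosolic calcium levels	MYL1
elevated cytosolic calcium levels	MYL6
elevated cytosolic calcium levels	MYLK2
elevated cytosolic calcium levels	TNNC1
elevated cytosolic calcium levels	TNNI1
elevated cytosolic calcium levels	TNNT1
elevated cytosolic calcium levels	TPM2
elevated cytosolic calcium levels	TPM3
elevated cytosolic calcium levels	TPM4
persistent contraction of muscle cell	MYH1
persistent contraction of muscle cell	TPM1
persistent contraction of muscle cell	TNNI2
persistent contraction of muscle cell	TNNT3
persistent contraction of muscle cell	TNNC1
persistent contraction of muscle cell	TNNI1
persistent contraction of muscle cell	TNNT1
persistent contraction of muscle cell	TPM2
persistent contraction of muscle cell	TPM3
persistent contraction of muscle cell	TPM4
glycogenolysis blockade	PYGM
glycogenolysis blockade	GBE1
glycogenolysis blockade	GYS1
glycogenolysis blockade	PHKA1
increased glucose uptake	SLC2A4
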