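id	group	age	sex	ck	severity	muscle	pygm_stain
C1	control	41	M	N.A.	NA	Biceps brachii	Normal
C2	control	27	F	<200	NA	Vastus lateralis	Normal
C3	control	35	F	<200	NA	Biceps brachii	Normal
C4	control	52	M	N.A.	NA	Biceps brachii	Normal
C5	control	35	M	<200	NA	Biceps brachii	Normal
C6	control	40	F	<200	NA	Biceps brachii	Normal
C7	control	56	F	<200	NA	Biceps brachii	Normal
C8	control	34	F	N.A.	NA	Vastus lateralis	Normal
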