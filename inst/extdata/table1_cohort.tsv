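id	group	age	sex	ck	severity	muscle	pygm_stain
P1	patient	19	F	1250	2	Biceps brachii	Absent
P2	patient	34	F	969	2	Biceps brachii	Absent
P3	patient	32	F	500	1	Vastus lateralis	Absent
P4	patient	24	M	533	2	Vastus lateralis	Absent
P5	patient	52	F	2328	2	Biceps brachii	Absent
P6	patient	48	M	4889	2	Biceps brachii	Absent
P7	patient	55	M	1330	2	Biceps brachii	Absent
P8	patient	43	M	1550	2	Biceps brachii	Absent
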