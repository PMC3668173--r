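row	block	SuSy1	SuSy2	SuSy3	SuSy4	SuSy5	printed_total	printed_bp_per_snp
S.officinarum	within	4	4	7	7	2	24	108
S.robustum	within	7	3	7	9	6	32	81
S.spontaneum	within	11	6	7	9	3	38	72
S.o+S.r	union	10	5	8	12	7	42	62
S.o+S.s	union	14	9	10	15	5	53	49
S.r+S.s	union	16	9	10	15	8	58	45
S.o+S.r+S.s	union	20	10	11	18	9	51	38
S.o&S.r	shared	2	2	6	4	1	15	172
S.o&S.s	shared	1	1	4	1	0	7	370
S.r&S.s	shared	3	0	4	3	1	11	238
S.o&S.r&S.s	shared	1	0	4	1	0	6	435
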