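row	SuSy1	SuSy2	SuSy3	SuSy4	SuSy5	printed_total
S.officinarum	1	1	4	3	3	12
S.robustum	1	2	3	4	1	11
S.spontaneum	1	2	3	2	1	9
total	1	3	5	7	3	19
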