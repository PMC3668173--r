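row	SuSy1	SuSy2	SuSy3	SuSy4	SuSy5	printed_total
S.officinarum	4	6	8	6	3	27
S.robustum	6	5	8	8	8	35
S.spontaneum	8	7	8	5	4	32
Total	15	15	16	17	11	74
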