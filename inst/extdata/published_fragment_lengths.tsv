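gene	length_bp
SuSy1	489
SuSy2	484
SuSy3	569
SuSy4	470
SuSy5	577
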