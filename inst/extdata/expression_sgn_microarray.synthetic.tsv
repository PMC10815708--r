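gene	sgn
Erbb3	2147
Ap4m1	0
Cops6	3310
Mcm7	905
Taf6	1122
Mir106b	0
Mir25	0
Mir93	0
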