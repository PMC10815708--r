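human_symbol	mouse_symbol
ERBB3	Erbb3
AP4M1	Ap4m1
COPS6	Cops6
MCM7	Mcm7
TAF6	Taf6
MIR106B	Mir106b
MIR25	Mir25
MIR93	Mir93
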