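gene	loeuf	pli
ERBB3	0.685	0
AP4M1	1.107	0
COPS6	0.374	1
MCM7	1.307	0
TAF6	0.657	0.55
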