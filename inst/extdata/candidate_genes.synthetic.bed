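chr12	56080025	56103505	ERBB3	1
chr7	100088000	100092000	COPS6	1
chr7	100092100	100101000	MCM7	1
chr7	100093560	100093643	MIR25	0
chr7	100094450	100094529	MIR93	0
chr7	100094855	100094936	MIR106B	0
chr7	100101200	100107000	TAF6	1
chr7	100107500	100113500	AP4M1	1
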