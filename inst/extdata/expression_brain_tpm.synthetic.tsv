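gene	Amygdala	ACC_BA24	Caudate	Cerebellar_Hemisphere	Cerebellum	Cortex	Frontal_Cortex_BA9	Hippocampus	Hypothalamus	Nucleus_accumbens	Putamen	Spinal_cord_c1	Substantia_nigra
ERBB3	34.2	41.5	38.0	55.6	60.3	44.1	47.8	36.9	33.5	39.2	37.4	58.0	31.7
AP4M1	9.8	11.2	10.5	13.4	14.0	12.1	12.8	10.0	9.1	10.7	10.2	8.9	8.4
COPS6	96.4	112.0	104.8	138.5	150.2	118.3	125.6	101.9	95.0	108.2	103.3	99.7	92.8
MCM7	27.3	31.8	29.6	41.2	44.9	33.5	35.7	28.4	26.1	30.9	29.0	25.5	24.8
TAF6	31.0	36.4	33.9	46.8	50.1	38.2	40.6	32.2	29.8	35.1	33.0	28.7	27.9
MIR106B	0	0	0	0	0	0	0	0	0	0	0	0	0
MIR25	0	0	0	0	0	0	0	0	0	0	0	0	0
MIR93	0	0	0	0	0	0	0	0	0	0	0	0	0
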