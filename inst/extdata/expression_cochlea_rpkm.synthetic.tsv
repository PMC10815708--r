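gene	hair_cells	non_hair_cells
Erbb3	45.2	62.8
Ap4m1	6.1	4.3
Cops6	88.4	95.6
Mcm7	30.5	22.7
Taf6	28.9	33.4
Mir106b	0	0
Mir25	0	0
Mir93	0	0
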