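chrom	start	end	svtype	freq_global	n_global	freq_subpop	n_subpop
12	56100029	56100167	DEL	8.74e-5	11	1.02e-4	6
12	56099811	56101058	DEL	2.38e-5	3	1.69e-5	1
12	56100244	56101058	DEL	1.27e-4	15	1.36e-4	8
12	56101363	56101526	DEL	1.35e-4	14	1.86e-4	11
7	100076358	100093492	DUP	3.17e-5	4	3.39e-5	2
7	100056545	100214180	DUP	7.93e-6	1	0	0
7	100095604	100095982	DUP	7.93e-6	1	0	0
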