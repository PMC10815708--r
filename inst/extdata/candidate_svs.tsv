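chrom	start	end	svtype	acmg	individuals
12	56100028	56100172	DEL	uncertain	I4-40,I4-41
12	56100243	56101058	DEL	uncertain	I4-40,I4-41
12	56101359	56101526	DEL	uncertain	I4-40,I4-41
7	100089053	100112257	DUP	uncertain	I4-28,I4-37
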