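# FrequentLy mutAted GeneS (FLAGS): recurrently mutated in any exome cohort
TTN
MUC16
OBSCN
AHNAK2
SYNE1
FLG
MUC5B
DNAH17
PLEC
DST
SYNE2
NEB
HSPG2
LAMA5
AHNAK
HMCN1
USH2A
DNAH11
MACF1
MUC17
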