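# Olfactory receptor genes
OR4F5
OR2T1
OR5AC2
OR1A1
OR2J2
OR10G4
OR51E2
OR2W1
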