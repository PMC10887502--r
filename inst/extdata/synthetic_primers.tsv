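primer_id	sequence	terminus
F1	GCCTATTAATRAAAACCAAAA	5p
F2	ATCAATTTGTCGTACTCCCTC	5p
F3	TCGATGATAATAAAACACTTC	5p
F4	TAACTTAATAGTACCCCACTC	5p
R1	GCCCTTTTATACTGAGATAGT	3p
R2	ATGAGAGTTCATGCCAAGCCA	3p
R3	TATGAATGTATTCAGTTTATC	3p
R4	CGATCGCATTAATATTAATAG	3p
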