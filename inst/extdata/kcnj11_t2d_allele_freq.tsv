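level	allele	variations	freq_control	freq_case
dna	KCNJ11*3	GCCGGGGCT	0.336	0.364
dna	KCNJ11*2	GCTGGGGCC	0.320	0.309
dna	KCNJ11*1	GCTGGGACC	0.317	0.301
dna	KCNJ11*5	GCCGCGGCT	0.015	0.018
dna	KCNJ11*8	GTTGGGGCC	0.008	0.006
dna	KCNJ11*4	GCTGGCGCC	0.0014	0.0005
dna	KCNJ11*6	GCCTGGGCT	0.00078	0.001
dna	KCNJ11*7	CCTGGGGCC	0.001	0.0003
dna	KCNJ11*13	GCTGGGGAC	0.0005	0
aa	KCNJ11*aa*5	EVLIS	0.647	0.616
aa	KCNJ11*aa*8	KVLVS	0.336	0.365
aa	KCNJ11*aa*9	KVVVS	0.015	0.018
aa	KCNJ11*aa*4	EVLIT	0.001	0.0003
aa	KCNJ11*aa*1	ELLIS	0.0005	0
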