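disorder	measure	age	rPh	r_trait_MZ	r_trait_DZ	r_diag_MZ	r_diag_DZ	r_cross_MZ	r_cross_DZ
ASD	A-TAC ASD	9-12	0.45	0.74	0.27	0.81	0.31	0.39	0.14
ADHD	A-TAC ADHD	9-12	0.52	0.69	0.23	0.88	0.44	0.47	0.17
ID	A-TAC learning	9-12	0.66	0.72	0.13	0.93	0.30	0.54	0.12
TD	A-TAC tics	9-12	0.48	0.44	0.11	0.64	-0.26	0.32	0.09
AD	SCARED	9	0.30	0.66	0.37	0.67	0.30	0.39	0.14
AD	SDQ-E parent	15	0.36	0.48	0.22	0.66	0.30	0.33	0.15
AD	SDQ-E self	15	0.26	0.44	0.18	0.66	0.30	0.23	0.07
AD	ABCL anxiety	18	0.40	0.57	0.32	0.65	0.30	0.30	0.16
AD	SCARED	18	0.42	0.49	0.17	0.65	0.30	0.42	0.17
MDD	SMFQ	9	0.22	0.55	0.29	0.68	0.37	0.56	0.03
MDD	SDQ-E parent	15	0.37	0.48	0.22	0.69	0.34	0.22	0.15
MDD	SDQ-E self	15	0.28	0.45	0.18	0.68	0.36	0.30	0.09
MDD	ABCL depression	18	0.44	0.52	0.26	0.66	0.35	0.34	0.14
MDD	CES-D	18	0.44	0.47	0.19	0.68	0.36	0.32	0.17
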