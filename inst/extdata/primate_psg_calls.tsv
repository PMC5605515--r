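branch	gene	twoDeltaL	p
Euarchontoglires	ARR3	4.02	0.045
Euarchontoglires	SWS1	11.65	6.415e-04
Dermoptera	CNGA1	7.27	0.007
Dermoptera	PDE6H	4.18	0.041
Strepsirrhini	GNGT1	6.11	0.013
Haplorrhini	CNGB1	9.49	0.002
Tarsiidae	PDE6B	8.44	0.004
Simiiformes	GRK1	3.89	0.048
Simiiformes	SWS1	6.89	0.009
Cebidae-stem	PDE6B	5.06	0.024
Cercopithecidae	CNGB3	7.78	0.005
Aotus	RCVRN	3.88	0.049
Glires	GNGT2	4.52	0.033
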