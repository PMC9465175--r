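Feature	A%	C%	G%	T%	A+T%	A+T skew	G+C skew
Whole genome	37.50	9.34	15.07	38.09	75.60	−0.008	−0.235
PCG	30.81	12.68	13.77	42.74	73.56	−0.162	−0.041
rRNA	39.03	5.89	12.46	42.63	81.66	−0.044	−0.358
tRNA	38.96	9.55	13.63	37.85	76.82	0.014	−0.176
A+T region	38.81	3.98	8.96	48.26	87.06	−0.109	−0.385
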