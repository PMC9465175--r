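codon	aa_printed	count	rscu_printed
UUU	F	117	1.44
UUC	F	45	0.56
UUA	L	199	2.80
UUG	L	53	0.75
CUU	L	53	0.75
CUC	L	23	0.32
CUA	L	78	1.10
CUG	L	20	0.28
AUU	I	168	1.02
AUC	I	73	0.44
AUA	M	254	1.54
AUG	M	59	1.00
GUU	V	21	1.00
GUC	V	11	0.52
GUA	V	40	1.90
GUG	V	12	0.57
UCU	S	30	1.10
UCC	S	18	0.66
UCA	S	55	2.01
UCG	S	7	0.26
CCU	P	18	0.87
CCC	P	29	1.40
CCA	P	27	1.30
CCG	P	9	0.43
ACU	U	49	1.15
ACC	U	43	1.01
ACA	U	67	1.58
ACG	U	11	0.26
GCU	A	7	0.80
GCC	A	8	0.91
GCA	A	19	2.17
GCG		1	0.11
UAU	Y	193	1.37
UAC	Y	88	0.63
UAA		263	2.10
UAG		81	0.65
CAU	H	69	1.21
CAC	H	45	0.79
CAA	Q	110	1.41
CAG	Q	46	0.59
AAU	N	234	1.34
AAC	N	114	0.66
AAA	K	248	1.45
AAG	K	95	0.55
GAU	D	56	1.51
GAC	D	18	0.49
GAA	E	70	1.33
GAG	E	35	0.67
UGU	C	22	1.29
UGC	C	12	0.71
UGA	W	32	0.26
UGG	W	25	1.00
CGU	R	14	0.78
CGC	R	6	0.33
CGA	R	7	0.39
CGG	R	8	0.44
AGU	S	29	1.06
AGC	S	25	0.91
AGA	S	38	2.11
AGG	S	35	1.94
GGU	G	16	1.14
GGC	G	7	0.50
GGA	G	14	1.00
GGG	G	19	1.36
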