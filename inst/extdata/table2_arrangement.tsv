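Gene	Direction	Location	Size (bp)	Anticodon	Start codon	Stop codon	Intergenic Nucleotides *
trnI	—	1–67	68	GAT		TA	−4
trnQ	+	65–133	79	TTG	TTA	TA	−2
trnM	—	133–199	67	CAT	AGA	—	5
nad2	—	203–1208	1006	—	ATC	TTA	−11
trnW	—	1209–1273	65	TCA		TA	−9
trnC	+	1266–1327	62	GCA		—	−1
trnY	+	1328–1390	83	GTA		TA	2
cox1	—	1392–2925	1534	—	ATG		−1
trnL2(UUR)	—	2926–2989	64	TAA		—	2
cox2	—	2990–3659	670	—	ATA	—	9
trnK	—	3660–3729	67	CTT		—	−2
trnD	—	3729–3795	76	GTC			−2
atp8	—	3796–3954	159	—	ATC	TAA	−5
atp6	—	3946–4625	678	—	ATG	—	8
cox3	—	4625–5413	789	—	ATG	TAA	4
trnG	—	5413–5477	65	TCC	ATT		2
nad3	—	5478–5829	352	—	ATT	T	6
trnA	—	5830–5894	65	TGC			−1
trnR	—	5895–5963	69	TCG			−1
trnN	—	5964–6027	64	GTT			−1
trnS1(AGN)	—	6027–6096	70	GCT			−1
trnE	—	6096–6159	64	TTC	ATT		0
trnF	+	6161–6223	63	GAA			3
nad5	+	6224–7946	1723	—	ATA	T	2
trnH	+	7947–8009	63	GTG		TT	−2
nad4	+	8009–9340	1332	—	TTA	T	−7
nad4L	+	9334–9624	291	—	TTA	T	2
trnT	—	9627–9688	62	TGT			−1
trnP	+	9689–9753	65	TGG		T	0
nad6	—	9755–10,234	480	—	ATA	TAA	5
cob	—	10,234–11,365	1132	—	ATG	T	2
trnS2(UCN)	—	11,366–11,433	68	TGA		TTA	−1
nad1	+	11,434–12,396	964	—	AAC	T	4
trnL1(CUN)	+	12,401–12,467	67	GTA	—	—	−31
rrnL	+	12,468–13,758	1258	—	—	T	2
trnV	+	13,759–13,826	68	TAC	—	—	0
rrnS	+	13,827–14,595	768	—	—	—	0
A+T-rich region		14,596–16060	1465	—	—	—	—
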