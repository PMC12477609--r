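name	sequence	salt	topology	conformer	grooves	tetrad_loop	groove_combination	handedness	gba	gba_stacks	reference
Bom-U16	TAGGTTAGGTTAGGTTAGG	K+	antiparallel	antiparallel chair	wnwn	2×−(lll)	II	-+	(sa)4	4sa	B33
148D	GGTTGGTGTGGTTGG	K+	antiparallel	antiparallel chair	wnwn	2×+(lll)	II	-+	(sa)4	4sa	B34
Hivpro1	TGGCCTGGGCGGGACTGGG	K+	antiparallel	antiparallel chair	wnwn	2×−(lll)	II	-+	(sa)4	4sa	B35
2KM3	AGGGCTAGGGCTAGGGCTAGGG	K+	antiparallel	antiparallel chair	wnwn	2×−(lll)	II	-+	(sa)4	4sa	B36
5YEY	GGGTTAGGGTTAGGGTTTGGG	K+	antiparallel	antiparallel chair	wnwn	3×+(lll)	II	-++	saa-ssa-saa-ssa	2aa·4sa·2ss	B37
5J4W	GGTTTGGTTTTGGTTGG	Na+	antiparallel	antiparallel basket	wmnm	2×(−ld+l)	VI	-+	(sa)4	4sa	B20
5J4P	GGTTTGGTTTTGGTTTGG	Na+	antiparallel	antiparallel basket	wmnm	2×(−ld+l)	VI	-+	(sa)4	4sa	B20
2M6V	GGGTTGGGTTTTGGGTGGG	Na+	antiparallel	antiparallel basket	wmnm	2×(−ld+l)	VI	-+	(sa)4	4sa	B20
6GZN	GGGTAGGGAGCGGGAGAGGG	K+	antiparallel	antiparallel basket	wmnm	2×(−ld+l)	VI	[-]-+[+]	sa[a]-sa[a-a]sa-sa[a]	[3aa·1as]·4sa	B38
5J05	GGGTTTGGGTTTTGGGAGGG	Na+	antiparallel	antiparallel basket	wmnm	3×(−ld+l)	VI	-+-	sas-asa-sas-asa	4as·4sa	B20
143D	AGGGTTAGGGTTAGGGTTAGGG	Na+	antiparallel	antiparallel basket	wmnm	3×(−ld+l)	VI	+-+	asa-sas-asa-sas	4as·4sa	B39
2MFT	GGGTTTTGGGTGGGTTTTGGG	Na+	antiparallel	antiparallel basket	wmnm	3×(d+pd)	VI	-++	saa-ssa-ssa-saa	2aa·4sa·2ss	B20
201D	GGGGTTTTGGGGTTTTGGGGTTTTGGGG	Na+	antiparallel	antiparallel basket	wmnm	4×(−ld+l)	VI	-+-+	(sasa)4	4as·8sa	B41
2M6W	GGGGTTGGGGTTTTGGGGAAGGGG	Na+	antiparallel	antiparallel basket	wmnm	4×(−ld+l)	VI	-+-+	(sasa)4	4as·8sa	B20
5J6U	GGGGTTTGGGGTTTTGGGGAAGGGG	Na+	antiparallel	antiparallel basket	wmnm	4×(−ld+l)	VI	-+-+	(sasa)4	4as·8sa	B20
2MFU	TGGGTTTGGGTTGGGTTTGGG	Na+	hybrid	hybrid	wnmm	2×−(llp)	III	-+	(sa)4	4sa	B40
6AC7	TGGGGTCCGAGGCGGGGCTTGGG	K+	hybrid	hybrid	wnmm	3×−(llp)	III	-++	saa-ssa-saa-saa	3aa·4sa·1ss	B42
7ALU	AGGGAGGTGTGGCCTGGGCGGG	K+	hybrid	hybrid	wnmm	3×−(llp)	III	-++	saa-ssa-saa-saa	3aa·4sa·1ss	B43
2JSL	TAGGGTTAGGGTTAGGGTTAGGGTT	K+	hybrid	hybrid	wnmm	3×−(llp)	III	-++	saa-ssa-saa-saa	3aa·4sa·1ss	B44
186D	TTGGGGTTGGGGTTGGGGTTGGGG	Na+	hybrid	hybrid	wnmm	3×−(llp)	III	-++	saa-ssa-saa-saa	3aa·4sa·1ss	B45
2GKU	TTGGGTTAGGGTTAGGGTTAGGGA	K+	hybrid	hybrid	mwnm	3×−(pll)	V	-++	saa-saa-ssa-saa	3aa·4sa·1ss	B46
2O3M	AGGGAGGGCGCTGGGAGGAGGG	K+	parallel	parallel	mmmm	3×(−p−p+p+p)	VIII	+++	(aaa)4	8aa	B47
1XAV	TGAGGGTGGGTAGGGTGGGTAA	K+	parallel	parallel	mmmm	3×−(ppp)	VIII	+++	(aaa)4	8aa	B48
2LPW	AAGGGTGGGTGTAAGTGTGGGTGGGT	K+	parallel	parallel	mmmm	3×−(ppp)	VIII	+++	(aaa)4	8aa	B49
2KYP	CGGGCGGGCGCTAGGGAGGGT	K+	parallel	parallel	mmmm	3×−(ppp)	VIII	+++	(aaa)4	8aa	B50
2LEE	TAGGGCGGGAGGGAGGGAA	K+	parallel	parallel	mmmm	3×−(ppp)	VIII	+++	(aaa)4	8aa	B51
2LXQ	TAGGGTGGGTTGGGTGGGGAAT	K+	parallel	parallel	mmmm	3×−(ppp)	VIII	+++	(aaa)4	8aa	B52
2M27	CGGGGCGGGCCTTGGGCGGGGT	K+	parallel	parallel	mmmm	3×−(ppp)	VIII	+++	(aaa)4	8aa	B53
DT2-L2T4	TTGGGTGGGTTTTGGGTGGGTT	Na+	parallel	parallel	mmmm	3×−(ppp)	VIII	+++	(aaa)4	8aa	B54
2xBlock2_T258-A	GAGGAGGAGGTGTTGTGGTGGTGGTG	K+	z-parallel	Z-parallel	mmmm	4×Z	Z	++--	(aaaa)4	8aa·4aa^5/6r	B55
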