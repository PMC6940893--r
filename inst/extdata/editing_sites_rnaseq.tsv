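morphotype	gene	position	strand	codon_from	codon_to	codon_position	aa_from	aa_to	effect_printed	phys_change_printed	level_1	level_2	level_3
purple	rps14	36640	-	UCA	UUA	2	S	L	nonsynonymous	TRUE	96	100	100
purple	petB	74797	+	CCA	CUA	2	P	L	nonsynonymous	FALSE	100	100	97
white	ndhB	138239	+	CCA	CUA	2	H	Y	nonsynonymous	FALSE	92	82	0
white	ndhD	113305	-	CUA	UUA	1	NA	NA	synonymous	FALSE	100	0	100
white	rbcL	55651	+	GCC	GCU	3	NA	NA	synonymous	FALSE	100	100	0
white	rbcL	55777	+	AUC	AUU	3	NA	NA	synonymous	FALSE	100	100	0
white	rps14	36572	-	UCA	UUA	2	S	L	nonsynonymous	TRUE	38	14	75
white	rps14	36497	-	CCA	CUA	2	P	L	nonsynonymous	FALSE	100	0	72
white	rps14	36553	-	AAC	AAU	3	NA	NA	synonymous	FALSE	100	100	0
white	psbB	72140	+	GGC	GGU	3	NA	NA	synonymous	FALSE	100	100	0
white	psbB	71372	+	UAC	UAU	3	NA	NA	synonymous	FALSE	100	0	100
white	psaA	39370	-	AUC	AUU	3	NA	NA	synonymous	FALSE	100	100	100
white	petB	74816	+	CCA	CUA	2	P	L	nonsynonymous	FALSE	100	0	97
yellow	rps14	36439	-	CCA	CUA	2	P	L	nonsynonymous	FALSE	69	71	NA
yellow	ccsA	111950	+	CUA	UUA	1	NA	NA	synonymous	FALSE	18	16	NA
yellow	petB	74948	+	CCA	CUA	2	P	L	nonsynonymous	FALSE	100	100	NA
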