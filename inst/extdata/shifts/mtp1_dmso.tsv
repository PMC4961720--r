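#! peptide_id=MTP1
#! sequence=KVSGVLFGTGLWVAL
#! c_terminus=amide
#! solvent=DMSO
#! temperature_K=298
#! reference=DMSO (2.5 ppm)
residue_index	residue	atom	shift_ppm	note
1	Lys	aCH	3.51
1	Lys	bCH	1.63
1	Lys	gCH	1.34
2	Val	NH	8.18
2	Val	aCH	4.28
2	Val	bCH	2.02
2	Val	gCH	0.84
3	Ser	NH	8.11
3	Ser	aCH	4.30
3	Ser	bCH	3.57
4	Gly	NH	8.06
4	Gly	aCH	3.775	mean of 3.81; 3.74
5	Val	NH	7.76
5	Val	aCH	4.19
5	Val	bCH	1.91
5	Val	gCH	0.74
6	Leu	NH	7.98
6	Leu	aCH	4.26
6	Leu	bCH	1.36
6	Leu	gCH	1.49
7	Phe	NH	7.92
7	Phe	aCH	4.53
7	Phe	bCH	3.02
7	Phe	bCH	2.84
8	Gly	NH	8.24
8	Gly	aCH	3.81
9	Thr	NH	7.81
9	Thr	aCH	4.21
9	Thr	bCH	4.08
9	Thr	gCH	1.06	gCH3
10	Gly	NH	8.08
10	Gly	aCH	3.76	mean of 3.81; 3.71
11	Leu	NH	7.87
11	Leu	aCH	4.33
11	Leu	bCH	1.39
11	Leu	gCH	1.51
12	Trp	NH	8.13
12	Trp	aCH	4.56
12	Trp	bCH	3.14
12	Trp	bCH	2.96
13	Val	NH	7.72
13	Val	aCH	4.18
13	Val	bCH	1.94
13	Val	gCH	0.83
14	Ala	NH	8.02
14	Ala	aCH	4.29
14	Ala	bCH	1.19
15	Leu	NH	7.72
15	Leu	aCH	4.18
15	Leu	bCH	1.43
15	Leu	gCH	1.58
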