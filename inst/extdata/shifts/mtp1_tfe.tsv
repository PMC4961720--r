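#! peptide_id=MTP1
#! sequence=KVSGVLFGTGLWVAL
#! c_terminus=amide
#! solvent=TFE_H2O_1_1
#! temperature_K=298
#! reference=TSP
residue_index	residue	atom	shift_ppm	note
1	Lys	aCH	4.11
1	Lys	bCH	1.98
1	Lys	gCH	1.51
2	Val	NH	8.45
2	Val	aCH	4.25
2	Val	bCH	2.12
2	Val	gCH	1.01
3	Ser	NH	8.16
3	Ser	aCH	4.55
3	Ser	bCH	3.95
3	Ser	bCH	3.88
4	Gly	NH	8.24
4	Gly	aCH	4.02
5	Val	NH	7.76
5	Val	aCH	4.12
5	Val	bCH	2.08
5	Val	gCH	0.95
6	Leu	NH	7.84
6	Leu	aCH	4.34
6	Leu	bCH	1.62
6	Leu	gCH	1.51
7	Phe	NH	7.78
7	Phe	aCH	4.34
7	Phe	bCH	3.10
7	Phe	bCH	3.01
8	Gly	NH	7.80
8	Gly	aCH	3.88	mean of 3.98; 3.78
9	Thr	NH	7.79
9	Thr	aCH	4.36
9	Thr	bCH	4.36
9	Thr	gCH	1.30	gCH3
10	Gly	NH	8.11
10	Gly	aCH	3.885	mean of 3.91; 3.86
11	Leu	NH	7.74
11	Leu	aCH	4.21
11	Leu	bCH	1.59
11	Leu	gCH	1.59
12	Trp	NH	7.60
12	Trp	aCH	4.43
12	Trp	bCH	3.35	single value listed
13	Val	NH	7.40
13	Val	aCH	3.72
13	Val	bCH	2.00
13	Val	gCH	0.85
14	Ala	NH	7.69
14	Ala	aCH	4.22
14	Ala	bCH	1.45
15	Leu	NH	7.80
15	Leu	aCH	4.30
15	Leu	bCH	1.78
15	Leu	gCH	1.62
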