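#! peptide_id=MTP2
#! sequence=MAEAHQAKAFQDT
#! c_terminus=amide
#! solvent=TFE_H2O_1_1
#! temperature_K=298
#! reference=TSP
residue_index	residue	atom	shift_ppm	note
1	Met	aCH	4.16
1	Met	bCH	2.24
1	Met	gCH	2.68
2	Ala	NH	8.61
2	Ala	aCH	4.43
2	Ala	bCH	1.45
3	Glu	NH	8.36
3	Glu	aCH	4.37
3	Glu	bCH	2.13
3	Glu	bCH	2.00
3	Glu	gCH	2.47
4	Ala	NH	8.20
4	Ala	aCH	4.29
4	Ala	bCH	1.39
5	His	NH	8.36
5	His	aCH	4.67
5	His	bCH	3.33
5	His	bCH	3.24
6	Gln	NH	8.31
6	Gln	aCH	4.36
6	Gln	bCH	2.15
6	Gln	bCH	2.05
6	Gln	gCH	2.39
7	Ala	NH	8.24
7	Ala	aCH	4.33
7	Ala	bCH	1.45
8	Lys	NH	8.04
8	Lys	aCH	4.30
8	Lys	bCH	1.84
8	Lys	gCH	1.48
9	Ala	NH	8.02
9	Ala	aCH	4.27
9	Ala	bCH	1.34
10	Phe	NH	7.90
10	Phe	aCH	4.58
10	Phe	bCH	3.21
10	Phe	bCH	3.12
11	Gln	NH	8.11
11	Gln	aCH	4.33
11	Gln	bCH	2.14
11	Gln	bCH	2.05
11	Gln	gCH	2.36
12	Asp	NH	8.30
12	Asp	aCH	4.78
12	Asp	bCH	2.97
12	Asp	bCH	2.86
13	Thr	NH	7.93
13	Thr	aCH	4.34
13	Thr	bCH	4.34
13	Thr	gCH	1.26	gCH3
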