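#! peptide_id=MTP2
#! sequence=MAEAHQAKAFQDT
#! c_terminus=amide
#! solvent=DMSO
#! temperature_K=298
#! reference=DMSO (2.5 ppm)
residue_index	residue	atom	shift_ppm	note
1	Met	aCH	3.84
1	Met	bCH	1.96
1	Met	gCH	2.51
2	Ala	NH	8.62
2	Ala	aCH	4.37
2	Ala	bCH	1.24
3	Glu	NH	8.15
3	Glu	aCH	4.27
3	Glu	bCH	1.89
3	Glu	bCH	1.73
3	Glu	gCH	2.25
4	Ala	NH	7.88
4	Ala	aCH	4.19
4	Ala	bCH	1.16
5	His	NH	8.12
5	His	aCH	4.45
5	His	bCH	2.91
6	Gln	NH	8.03
6	Gln	aCH	4.17
6	Gln	bCH	1.87
6	Gln	bCH	1.72
6	Gln	gCH	2.08
7	Ala	NH	8.38
7	Ala	aCH	4.25
7	Ala	bCH	1.21
8	Lys	NH	7.90
8	Lys	aCH	4.19
8	Lys	bCH	1.62
8	Lys	gCH	1.28
9	Ala	NH	8.08
9	Ala	aCH	4.25
9	Ala	bCH	1.19
10	Phe	NH	7.94
10	Phe	aCH	4.47
10	Phe	bCH	3.04
10	Phe	bCH	2.81
11	Gln	NH	8.09
11	Gln	aCH	4.24
11	Gln	bCH	1.84
11	Gln	bCH	1.77
11	Gln	gCH	2.10
12	Asp	NH	8.33
12	Asp	aCH	4.62
12	Asp	bCH	2.74
12	Asp	bCH	2.56
13	Thr	NH	7.51
13	Thr	aCH	4.86
13	Thr	bCH	4.06
13	Thr	gCH	1.00	gCH3
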