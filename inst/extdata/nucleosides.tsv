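name	abbreviation	formula	glycosidic_bond	sugar_mod	product_overrides	printed_precursor	printed_product	alt_precursor	alt_product	family	provenance
Adenosine	A	C10H13N5O4	N	none				 	 	A	sec1
Cytidine	C	C9H13N3O5	N	none		244.1	112	 	 	C	sec2;sec3
Guanosine	G	C10H13N5O5	N	none				 	 	G	sec1
Uridine	U	C9H12N2O6	N	none		245.1	113	 	 	U	sec2;sec3
Inosine	I	C10H12N4O5	N	none		269.1	137	 	 	other	sec1
Pseudouridine	Y	C9H12N2O6	C	none	209;179;155	245.1		 	 	U	sec2;sec3
1-Methyladenosine	m1A	C11H15N5O4	N	none		282.1	150	 	 	A	table1;table3;sec2
2-Methyladenosine	m2A	C11H15N5O4	N	none		282.1	150	 	 	A	table1;table3;sec2
N6-Methyladenosine	m6A	C11H15N5O4	N	none		282.1	150	 	 	A	table1;table3;sec2
8-Methyladenosine	m8A	C11H15N5O4	N	none		282.1	150	 	 	A	table1
2,8-Dimethyladenosine	m2,8A	C12H17N5O4	N	none		296.1	164	269.1	 	A	table1;table2
N6,N6-Dimethyladenosine	m6,6A	C12H17N5O4	N	none		296.1	164	269.1	 	A	table1;table2;sec2
N6-Formyladenosine	f6A	C11H13N5O5	N	none		269.1	164	 	 	A	table2;sec2
N6-Methyl-N6-threonylcarbamoyladenosine	m6t6A	C15H20N6O8	N	none		427.2	295	 	 	A	table2
N6-Hydroxynorvalylcarbamoyladenosine	hn6A	C16H22N6O8	N	none		427.2	295	 	 	A	table2
2'-O-Methyladenosine	Am	C11H15N5O4	N	2'-O-methyl		282.1	136	 	 	A	table3
1,2'-O-Dimethyladenosine	m1Am	C12H17N5O4	N	2'-O-methyl		296.1	150	 	 	A	table3
1-Methylinosine	m1I	C11H14N4O5	N	none		283.1	151	 	 	other	table3;sec2
2'-O-Methylinosine	Im	C11H14N4O5	N	2'-O-methyl		283.1	137	 	 	other	table3
1,2'-O-Dimethylinosine	m1Im	C12H16N4O5	N	2'-O-methyl		297.1	151	 	 	other	table3
3-Methylcytidine	m3C	C10H15N3O5	N	none		258.1	126	 	 	C	table1;table3
N4-Methylcytidine	m4C	C10H15N3O5	N	none		258.1	126	 	 	C	table1;table3
5-Methylcytidine	m5C	C10H15N3O5	N	none		258.1	126	 	 	C	table1;table3
3-Methyluridine	m3U	C10H14N2O6	N	none		259.1	127	 	 	U	table1;table3
5-Methyluridine	m5U	C10H14N2O6	N	none		259.1	127	 	 	U	table1;table3
1-Methylpseudouridine	m1Y	C10H14N2O6	C	none	179	259.1	179	 	 	U	table1
3-Methylpseudouridine	m3Y	C10H14N2O6	C	none	179	259.1	179	 	 	U	table1
2-Thiocytidine	s2C	C9H13N3O4S	N	none		260.1	128	 	 	C	table2;table3;sec2
5-Hydroxycytidine	ho5C	C9H13N3O6	N	none		260.1	128	 	 	C	table2;table3
2-Thiouridine	s2U	C9H12N2O5S	N	none		261.1	129	 	 	U	table1;table2;table3;sec2
4-Thiouridine	s4U	C9H12N2O5S	N	none		261.1	129	 	 	U	table1;table2;table3;sec2
5-Hydroxyuridine	ho5U	C9H12N2O7	N	none		261.1	129	 	 	U	table2;table3;sec2
5-Methyldihydrouridine	m5D	C10H16N2O6	N	none		261.1	129	 	 	U	table2;table3;sec2
5-Formylcytidine	f5C	C10H13N3O6	N	none		272.1	140	 	 	C	table2
N4,N4-Dimethylcytidine	m4,4C	C11H17N3O5	N	none		272.1	140	 	 	C	table2
5,2'-O-Dimethylcytidine	m5Cm	C11H17N3O5	N	2'-O-methyl		272.1	126	 	 	C	table1;table3
N4,2'-O-Dimethylcytidine	m4Cm	C11H17N3O5	N	2'-O-methyl		272.1	126	 	 	C	table1;table3
3,2'-O-Dimethyluridine	m3Um	C11H16N2O6	N	2'-O-methyl		273.1	127	 	 	U	table1;table3
5,2'-O-Dimethyluridine	m5Um	C11H16N2O6	N	2'-O-methyl		273.1	127	 	 	U	table1;table3
5-Hydroxymethylcytidine	hm5C	C10H15N3O6	N	none		274.1	142	 	 	C	table3
5-Aminomethyluridine	nm5U	C10H15N3O6	N	none		274.1	142	 	 	U	table3
5-Methyl-2-thiouridine	m5s2U	C10H14N2O5S	N	none		275.1	143	 	 	U	table2;table3
5-Methoxyuridine	mo5U	C10H14N2O7	N	none		275.1	143	 	 	U	table2;table3
5-Cyanomethyluridine	cnm5U	C11H13N3O6	N	none		284.1	152	 	 	U	table3
N4-Acetylcytidine	ac4C	C11H15N3O6	N	none		286.1	154	 	 	C	table3
5-Formyl-2'-O-methylcytidine	f5Cm	C11H15N3O6	N	2'-O-methyl		286.1	140	 	 	C	table2;table3
N4,N4,2'-O-Trimethylcytidine	m4,4Cm	C12H19N3O5	N	2'-O-methyl		286.1	140	 	 	C	table2;table3
2'-O-Methyl-5-hydroxymethylcytidine	hm5Cm	C11H17N3O6	N	2'-O-methyl		288.1	142	 	 	C	table3
5-Methylaminomethyluridine	mnm5U	C11H17N3O6	N	none		288.1	156	 	 	U	table3
5-Aminomethyl-2-thiouridine	nm5s2U	C10H15N3O5S	N	none		290.1	158	 	 	U	table3
5-Carbamoylmethyluridine	ncm5U	C11H15N3O7	N	none		302.1	170	 	 	U	table3
5-Carboxymethyluridine	cm5U	C11H14N2O8	N	none		303.1	171	 	 	U	table3
5-Methylaminomethyl-2-thiouridine	mnm5s2U	C11H17N3O5S	N	none		304.1	172	 	 	U	table3
5-Methoxycarbonylmethyluridine	mcm5U	C12H16N2O8	N	none		317.1	185	 	 	U	table3
5-Carbamoylmethyl-2-thiouridine	ncm5s2U	C11H15N3O6S	N	none		318.1	186	 	 	U	table2;table3
5-Carbamoylhydroxymethyluridine	nchm5U	C11H15N3O8	N	none		318.1	186	 	 	U	table2;table3
5-Carboxymethyl-2-thiouridine	cm5s2U	C11H14N2O7S	N	none		319.1	187	 	 	U	table2;table3
5-Carboxyhydroxymethyluridine	chm5U	C11H14N2O9	N	none		319.1	187	 	 	U	table1;table2;table3
Uridine 5-oxyacetic acid	cmo5U	C11H14N2O9	N	none		319.1	187	 	 	U	table1;table2;table3
5-Carboxymethylaminomethyluridine	cmnm5U	C12H17N3O8	N	none		332.1	200	 	 	U	table3
5-Methoxycarbonylmethyl-2-thiouridine	mcm5s2U	C12H16N2O7S	N	none		333.1	201	 	 	U	table2;table3
5-(Carboxyhydroxymethyl)uridine methyl ester	mchm5U	C12H16N2O9	N	none		333.1	201	 	297	U	table1;table2;table3
Uridine 5-oxyacetic acid methyl ester	mcmo5U	C12H16N2O9	N	none		333.1	201	 	297	U	table1;table2;table3
3-(3-Amino-3-carboxypropyl)pseudouridine	acp3Y	C13H19N3O8	C	none	214	346.1	214	 	 	U	table1
3-(3-Amino-3-carboxypropyl)uridine	acp3U	C13H19N3O8	N	none		346.1	214	 	 	U	table1
5-Carboxymethylaminomethyl-2-thiouridine	cmnm5s2U	C12H17N3O7S	N	none		348.1	216	 	 	U	table2
3-(3-Amino-3-carboxypropyl)-5,6-dihydrouridine	acp3D	C13H21N3O8	N	none		348.1	216	 	 	U	table2
5-Carboxymethylaminomethyl-2'-O-methyluridine	cmnm5Um	C13H19N3O8	N	2'-O-methyl		346.1	200	 	 	U	table3
5-(Carboxyhydroxymethyl)-2'-O-methyluridine methyl ester	mchm5Um	C13H18N2O9	N	2'-O-methyl		347.1	201	 	 	U	table3
2'-O-Methyluridine 5-oxyacetic acid methyl ester	mcmo5Um	C13H18N2O9	N	2'-O-methyl		347.1	201	 	 	U	table3
5-(Isopentenylaminomethyl)-2-thiouridine	inm5s2U	C15H23N3O5S	N	none		358.1	226	 	 	U	table3
1-Methyl-3-(3-amino-3-carboxypropyl)pseudouridine	m1acp3Y	C14H21N3O8	C	none	228	360.1	228	 	 	U	table3
1-Methylguanosine	m1G	C11H15N5O5	N	none		298.1	166	 	 	G	table1;sec2
N2-Methylguanosine	m2G	C11H15N5O5	N	none		298.1	166	 	 	G	table1;sec2
7-Methylguanosine	m7G	C11H15N5O5	N	none		298.1	166	 	 	G	table1;sec2
1,2'-O-Dimethylguanosine	m1Gm	C12H17N5O5	N	2'-O-methyl		312.1	166	 	 	G	table1
N2,2'-O-Dimethylguanosine	m2Gm	C12H17N5O5	N	2'-O-methyl		312.1	166	 	 	G	table1
N2,7-Dimethylguanosine	m2,7G	C12H17N5O5	N	none		312.1	180	 	 	G	table1
N2,N2-Dimethylguanosine	m2,2G	C12H17N5O5	N	none		312.1	180	 	 	G	table1
N2,N2,2'-O-Trimethylguanosine	m2,2Gm	C13H19N5O5	N	2'-O-methyl		326.1	180	 	 	G	table1
N2,7,2'-O-Trimethylguanosine	m2,7Gm	C13H19N5O5	N	2'-O-methyl		326.1	180	 	 	G	table1
Isowyosine	imG2	C14H17N5O5	N	none		336.1	204	 	 	G	table1
Wyosine	imG	C14H17N5O5	N	none		336.1	204	 	 	G	table1
7-Aminocarboxypropylwyosine methyl ester	yW-58	C19H26N6O7	N	none		451.2	319	 	 	G	table3
Undermodified hydroxywybutosine	OHyWx	C18H24N6O8	N	none		453.2	321	 	 	G	table3
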