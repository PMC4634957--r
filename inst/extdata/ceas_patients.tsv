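patient	pedigree_id	ascertainment	sex	consanguineous	consanguinity_degree	family_history	mutation_classes	allele1	allele2	onset_age	diagnosis_age	symptoms	sites	hemoglobin	serum_protein	crp	surgery
1	A-V-2	exome	F	yes	5	no	SS/SS	c.1461+1G>C	c.1461+1G>C	17	43	Anemia	I	9.6	4.6	0.5	+
2	B-IV-3	exome	F	yes	3	no	SS/SS	c.940+1G>A	c.940+1G>A	37	38	Anemia	S,I	9.5	6.7	0.5	+
3	C-IV-3	exome	F	yes	3	no	SS/SS	c.940+1G>A	c.940+1G>A	11	39	Anemia, abdominal pain	I	NA	NA	NA	+
4	D-II-4	exome	F	no	NA	yes	NS/NS	c.664G>A	c.1807C>T	53	55	Anemia	S,I	9.7	5.2	0.1	-
5	D-II-5	exome	F	no	NA	yes	NS/NS	c.664G>A	c.1807C>T	12	22	Anemia, abdominal pain	S,D,I	9.7	5.8	0.3	+
6	NA	sanger	F	no	NA	yes	SS/SS	c.940+1G>A	c.940+1G>A	12	51	Anemia	D,I	4.8	5.3	0.0	+
7	NA	sanger	F	no	NA	yes	SS/SS	c.940+1G>A	c.940+1G>A	16	41	Anemia	D,I	10.7	5.8	0.9	+
8	NA	sanger	F	yes	3	no	SS/SS	c.940+1G>A	c.940+1G>A	13	29	Anemia	D,I	8.4	5.0	0.2	+
9	NA	sanger	F	yes	3	no	NS/NS	c.1372G>T	c.1372G>T	40	66	Anemia, hypoproteinemia	I	9.5	4.4	0.6	+
10	NA	sanger	F	no	NA	no	NS/NS	c.421G>T	c.1807C>T	50	59	Anemia, abdominal pain	I	8.5	6.3	0.1	-
11	NA	sanger	M	no	NA	no	SS/SS	c.940+1G>A	c.940+1G>A	20	41	Anemia, hypoproteinemia	D,J,I	11.0	4.8	1.6	-
12	NA	sanger	M	no	NA	no	NS/NS	c.664G>A	c.664G>A	15	63	Anemia, hypoproteinemia	J,I	8.1	5.7	0.4	+
13	NA	sanger	F	yes	3	no	SS/SS	c.940+1G>A	c.940+1G>A	51	51	Anemia, abdominal pain	S,I	11.2	6.6	0.1	+
14	NA	sanger	F	yes	3	yes	SS/SS	c.940+1G>A	c.940+1G>A	7	7	Anemia, abdominal pain	S,D,J,I	11.1	5.8	0.1	+
15	NA	sanger	F	no	NA	no	SS/NS	c.940+1G>A	c.1807C>T	18	23	Anemia, abdominal pain	D,I	7.8	3.8	0.0	+
16	NA	sanger	M	yes	NA	no	SS/SS	c.940+1G>A	c.940+1G>A	12	31	Anemia, edema	D,I	7.4	8.2	0.1	+
17	NA	cd_screen	M	no	NA	no	SS/NS	c.940+1G>A	c.547G>A	1	NA	Anemia, edema	J,I	2.3	5.1	0.4	+
18	NA	cd_screen	F	no	NA	no	SS/NS	c.940+1G>A	c.421G>T	52	NA	Anemia, edema	J,I	9.5	5.2	0.1	-
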