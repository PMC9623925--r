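# Published phenotype-spectrum counts for each P/LP CNV region of the
# bundled case study, as extracted from a DECIPHER-style patient database:
# syn_n / syn_N syndromic-CHD carriers over all region-matched patients
# (syn_pct as published), iso_n isolated-CHD carriers over the same
# denominator (iso_pct as published, empty when zero).
no	copy_state	region	syn_n	syn_N	syn_pct	iso_n	iso_pct
1	dup	8q24.21-q24.3	7	134	5.2	0	NA
2	del	13q33.1-q34	27	172	15.7	1	0.6
3	del	1p36.33	25	195	12.8	0	NA
4	del	2p16.3	0	12	0.0	0	NA
5	del	3q25.33-q26.1	1	9	11.1	0	NA
6	del	22q11.21	170	745	22.8	22	3.0
7	del	2q13	2	58	3.4	0	NA
8	dup	Xp22.31	8	269	3.0	3	1.1
9	del	17q25.3	2	11	18.2	0	NA
10	del	5q35.3	8	27	29.6	0	NA
11	del	1q43-q44	25	199	12.6	0	NA
12	del	6q14.1-q16.1	12	84	14.3	0	NA
13	dup	15q11.2	6	257	2.3	0	NA
14	del	11q23.3-q25	66	247	26.7	1	0.4
15	del	17p13.3	29	91	31.9	0	NA
16	dup	18p11.31-p11.23	21	139	15.1	1	0.7
17	dup	7q34-q36.3	9	100	9.0	2	2.0
18	dup	Xq26.2	2	35	5.7	0	NA
19	del	5p15.33-p15.31	31	179	17.3	1	0.6
20	dup	5p15.31-p14.1	11	125	8.8	1	0.8
21	dup	3p26.3-p24.2	19	302	6.3	3	1.0
22	del	9p24.3-p22.3	53	300	17.7	1	0.3
23	dup	9p22.3	5	43	11.6	0	NA
24	del	16q21-q22.1	5	28	17.9	0	NA
25	del	17p11.2	13	97	13.4	0	NA
26	del	3p22.2	1	2	50.0	0	NA
27	dup	6p25.3-p22.2	12	118	10.2	0	NA
28	del	15q26.3	20	117	17.1	0	NA
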