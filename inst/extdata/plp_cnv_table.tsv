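# Pathogenic / likely pathogenic CNV table of the bundled 109-patient
# syndromic-CHD case study: one row per reported CNV with the three
# published verdict columns (MVP category + score, curated-region verdict,
# gene-evidence verdict). size_printed_mb is the size as published;
# size_consistent records whether that size matches the printed coordinates
# under the end-start length convention and half-up display rounding.
patient	sex	copy_state	region	size_printed_mb	range	mvp_category	mvp_score	decipher_category	omim_category	size_consistent	cardiac_terms
5	M	dup	8q24.21-q24.3	17.7	Chr8:128,538,700-146,262,124	pathogenic	0.862	pathogenic	pathogenic	TRUE	ASD
5	M	del	13q33.1-q34	11.9	Chr13:103,226,118-115,091,802	pathogenic	0.840	pathogenic	pathogenic	TRUE	ASD
11	M	del	1p36.33	1.3	Chr1:849,466-2,174,235	pathogenic	0.840	pathogenic	pathogenic	TRUE	VSD
12	M	del	2p16.3	0.03	Chr2:50,203,462-50,232,894	benign	0.123	NM	pathogenic	TRUE	TOF;RAA
17	M	del	3q25.33-q26.1	0.2	Chr3:160,526,260-160,738,728	likely_pathogenic	0.527	likely_benign	NM	TRUE	DORV;TGA;VSD;PS;PDA
32	M	del	22q11.21	2.5	Chr22:18,921,359-21,460,595	pathogenic	0.840	pathogenic	pathogenic	TRUE	TOF;RAA
33	M	del	2q13	1.7	Chr2:111,398,336-113,101,220	likely_pathogenic	0.527	uncertain	pathogenic	TRUE	ASD
34	M	dup	Xp22.31	0.5	ChrX:6,836,073-7,347,549	likely_benign	0.154	likely_pathogenic	NM	TRUE	VSD
38	F	del	17q25.3	0.8	Chr17:79,344,285-80,192,099	likely_pathogenic	0.527	NM	pathogenic	TRUE	VSD;ASD
43	F	del	5q35.3	0.6	Chr5:180,069,797-180,686,444	likely_pathogenic	0.527	NM	pathogenic	TRUE	VSD
44	M	del	1q43-q44	5.5	Chr1:243,545,786-249,208,146	likely_pathogenic	0.527	pathogenic	pathogenic	FALSE	ASD
53	M	del	6q14.1-q16.1	11.0	Chr6:83,849,802-95,155,354	likely_pathogenic	0.544	pathogenic	pathogenic	FALSE	VSD;ASD
60	M	dup	15q11.2	1.0	Chr15:24,050,216-25,107,421	uncertain	0.187	uncertain	likely_pathogenic	FALSE	solitary dextrocardia;complete AVSD;anatomical DORV with TGA;PVS
66	M	del	22q11.21	2.5	Chr22:18,919,528-21,460,595	pathogenic	0.840	pathogenic	pathogenic	TRUE	VSD
75	F	del	11q23.3-q25	13.5	Chr11:121,057,903-134,928,850	pathogenic	0.840	pathogenic	pathogenic	FALSE	DORV;CoA
76	M	del	17p13.3	0.2	Chr17:226,043-438,909	likely_pathogenic	0.544	NM	pathogenic	TRUE	VSD
76	M	dup	18p11.31-p11.23	0.5	Chr18:7,086,919-7,605,032	uncertain	0.282	NM	pathogenic	TRUE	VSD
77	F	dup	7q34-q36.3	19.1	Chr7:139,520,175-159,123,167	pathogenic	0.862	pathogenic	pathogenic	FALSE	VSD
96	F	dup	Xq26.2	0.1	ChrX:133,025,264-133,159,421	likely_benign	0.141	NM	pathogenic	TRUE	ASD
99	F	del	5p15.33-p15.31	7.8	Chr5:113,576-8,101,272	pathogenic	0.840	pathogenic	pathogenic	FALSE	VSD
99	F	dup	5p15.31-p14.1	19.1	Chr5:8,115,306-27,645,325	pathogenic	0.862	pathogenic	pathogenic	FALSE	VSD
102	M	dup	3p26.3-p24.2	25.7	Chr3:105,511-25,830,553	pathogenic	0.862	pathogenic	pathogenic	TRUE	VSD;ASD
103	F	del	9p24.3-p22.3	14.5	Chr9:204,149-14,724,068	pathogenic	0.840	pathogenic	pathogenic	TRUE	ASD
103	F	dup	9p22.3	1.6	Chr9:14,762,293-16,349,620	likely_benign	0.141	likely_pathogenic	pathogenic	TRUE	ASD
103	F	dup	10p15.1-p14	1.0	Chr10:6,547,235-7,565,244	likely_benign	0.141	uncertain	NM	TRUE	ASD
104	M	del	16q21-q22.1	1.4	Chr16:66,280,192-67,654,588	likely_pathogenic	0.527	NM	likely_pathogenic	TRUE	VSD;ASD;PDA
107	M	del	17p11.2	3.7	Chr17:16,603,146-20,274,157	pathogenic	0.840	pathogenic	pathogenic	TRUE	VSD
108	F	del	3p22.2	0.6	Chr3:38,455,532-39,035,153	pathogenic	0.854	pathogenic	pathogenic	TRUE	ASD;PVS
109	F	dup	6p25.3-p22.2	24.7	Chr6:390,212-25,638,706	pathogenic	0.862	likely_pathogenic	pathogenic	FALSE	PDA
109	F	del	15q26.3	1.0	Chr15:101,341,696-102,391,143	pathogenic	0.840	uncertain	likely_pathogenic	TRUE	PDA
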