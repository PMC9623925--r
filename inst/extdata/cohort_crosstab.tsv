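# Published CHD-category x primary-extracardiac-comorbidity cross-tabulation
# of the bundled 109-patient syndromic-CHD case study (counts). Classes:
# A septal defects; B isolated valve abnormalities; C septal defects with
# valve abnormalities; D LVOT obstruction; E isolated conotruncal defects;
# F compound conotruncal defects; G heterotaxy syndrome; H others.
# representative_terms: a cardiac term combination mapping to the class
# under chdCategory(), used to expand the table into a patient-level cohort.
class	Neurodevelopmental	Genitourinary	Craniofacial	Digestive	Limbs	Musculoskeletal	Respiratory	Endocrine	Others	representative_terms
A	30	10	7	7	4	7	2	4	1	VSD
B	0	1	0	0	0	0	0	1	1	MR
C	2	0	2	0	1	0	0	0	0	VSD;MR
D	2	1	1	2	0	0	1	1	0	CoA
E	0	0	0	1	0	1	0	0	1	TOF
F	3	0	2	1	0	3	0	0	2	TOF;VSD
G	0	0	1	0	0	0	0	0	0	heterotaxy syndrome
H	0	0	0	0	1	0	4	0	1	PDA
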