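# Cardiac phenotype vocabulary: terms treated as cardiac by
# classifyPatient(); matching is exact after case-folding.
# Abbreviations
VSD
ASD
AVSD
TOF
DORV
TGA
PDA
PS
MS
MR
TR
AS
CoA
RAA
PVS
PA
PAPVC
PAS
SV
# Full terms as used in clinical phenotype databases
Ventricular septal defect
Atrial septal defect
Atrioventricular septal defect
Complete atrioventricular septal defect
Complete AVSD
Atrioventricular canal defect
Tetralogy of Fallot
Double outlet right ventricle
Anatomical DORV with TGA
Transposition of the great arteries
Patent ductus arteriosus
Pulmonic stenosis
Pulmonary stenosis
Pulmonary valve stenosis
Pulmonary artery stenosis
Pulmonary atresia
Mitral stenosis
Mitral regurgitation
Tricuspid regurgitation
Aortic regurgitation
Aortic stenosis
Aortic valve stenosis
Supravalvular aortic stenosis
Bicuspid aortic valve
Supramitral stenosing ring
Coarctation of the aorta
Interrupted aortic arch
Truncus arteriosus
Hypoplastic left heart
Hypoplastic left heart syndrome
Sinus venosus atrial septal defect
Single ventricle
Right aortic arch
Solitary dextrocardia
Dextrocardia
Heterotaxy syndrome
Heterotaxy
Abnormal heart morphology
Abnormality of cardiovascular system morphology
Abnormality of the cardiovascular system
Abnormal cardiac septum morphology
Abnormal ventricular septum morphology
Abnormal aortic valve morphology
Abnormal atrioventricular valve morphology
Partial anomalous pulmonary venous connection
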