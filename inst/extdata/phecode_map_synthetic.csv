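icd_code,vocabulary,phecode,description,domain
F41.9,ICD10CM,300.1,anxiety disorder,mental disorders
300.00,ICD9CM,300.1,anxiety disorder,mental disorders
F32.9,ICD10CM,296.2,depression,mental disorders
311,ICD9CM,296.2,depression,mental disorders
F33.1,ICD10CM,296.22,major depressive disorder,mental disorders
F17.200,ICD10CM,318,tobacco use disorder,mental disorders
F20.9,ICD10CM,295.1,schizophrenia,mental disorders
F10.20,ICD10CM,317,alcoholism,mental disorders
C80.1,ICD10CM,195,malignant neoplasm,neoplasms
C79.9,ICD10CM,198,secondary malignant neoplasm,neoplasms
C61,ICD10CM,185,prostate cancer,neoplasms
C50.911,ICD10CM,174.1,breast cancer,neoplasms
C18.9,ICD10CM,153,colorectal cancer,neoplasms
C34.90,ICD10CM,165.1,lung cancer,neoplasms
G43.909,ICD10CM,340,migraine,neurological
G47.00,ICD10CM,327,sleep disorders,neurological
G20,ICD10CM,332,parkinson disease,neurological
G40.909,ICD10CM,345,epilepsy,neurological
G62.9,ICD10CM,356,peripheral neuropathy,neurological
E11.9,ICD10CM,250.2,type 2 diabetes,endocrine/metabolic
250.00,ICD9CM,250.2,type 2 diabetes,endocrine/metabolic
E78.5,ICD10CM,272.1,hyperlipidemia,endocrine/metabolic
E03.9,ICD10CM,244,hypothyroidism,endocrine/metabolic
E66.9,ICD10CM,278.1,obesity,endocrine/metabolic
E78.00,ICD10CM,272.11,hypercholesterolemia,endocrine/metabolic
I10,ICD10CM,401.1,essential hypertension,circulatory system
401.1,ICD9CM,401.1,essential hypertension,circulatory system
I25.10,ICD10CM,411.4,coronary atherosclerosis,circulatory system
I48.91,ICD10CM,427.2,atrial fibrillation,circulatory system
I50.9,ICD10CM,428.2,heart failure,circulatory system
J45.909,ICD10CM,495,asthma,respiratory
493.90,ICD9CM,495,asthma,respiratory
J44.9,ICD10CM,496,chronic airway obstruction,respiratory
J32.9,ICD10CM,475,chronic sinusitis,respiratory
R06.02,ICD10CM,512.7,shortness of breath,respiratory
R05,ICD10CM,512.8,cough,respiratory
K21.9,ICD10CM,530.11,gastroesophageal reflux disease,digestive
K29.70,ICD10CM,535,gastritis,digestive
K59.00,ICD10CM,563,constipation,digestive
D64.9,ICD10CM,285,anemia,hematopoietic
H40.9,ICD10CM,365,glaucoma,sense organs
R10.9,ICD10CM,785,abdominal pain,symptoms
M19.90,ICD10CM,740.1,osteoarthrosis,musculoskeletal
M54.5,ICD10CM,760,low back pain,musculoskeletal
N18.9,ICD10CM,585.3,chronic kidney disease,genitourinary
N39.0,ICD10CM,591,urinary tract infection,genitourinary
S01.90XA,ICD10CM,870,open wound of head,injuries & poisoning
O26.90,ICD10CM,637,pregnancy complication,pregnancy complications
L08.9,ICD10CM,686.1,skin infection,dermatologic
Q89.9,ICD10CM,747.1,congenital anomaly,congenital anomalies
A09,ICD10CM,8,intestinal infection,infectious diseases
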