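code	label
A15	Respiratory tuberculosis
B18	Chronic viral hepatitis
B20	HIV disease
C34	Malignant neoplasm of bronchus and lung
C50	Malignant neoplasm of breast
C61	Malignant neoplasm of prostate
D50	Iron deficiency anaemia
D64	Other anaemias
D69	Purpura and other haemorrhagic conditions
D70	Agranulocytosis
E03	Hypothyroidism
E04	Nontoxic goitre
E10	Type 1 diabetes mellitus
E11	Type 2 diabetes mellitus
E14	Unspecified diabetes mellitus
E66	Obesity
E77	Disorders of glycoprotein metabolism
E78	Disorders of lipoprotein metabolism
E79	Disorders of purine and pyrimidine metabolism
F03	Dementia
F20	Schizophrenia
F32	Depressive episode
F41	Other anxiety disorders
G20	Parkinson disease
G40	Epilepsy
G47	Sleep disorders
G93	Other disorders of brain
H25	Senile cataract
H26	Other cataract
H81	Disorders of vestibular function
I10	Essential hypertension
I11	Hypertensive heart disease
I20	Angina pectoris
I21	Acute myocardial infarction
I22	Subsequent myocardial infarction
I23	Complications following myocardial infarction
I24	Other acute ischaemic heart diseases
I25	Chronic ischaemic heart disease
I27	Other pulmonary heart diseases
I44	Atrioventricular and left bundle-branch block
I45	Other conduction disorders
I47	Paroxysmal tachycardia
I48	Atrial fibrillation and flutter
I49	Other cardiac arrhythmias
I50	Heart failure
I51	Complications and ill-defined heart disease
I63	Cerebral infarction
I65	Occlusion of precerebral arteries
I67	Other cerebrovascular diseases
I69	Sequelae of cerebrovascular disease
I70	Atherosclerosis
I83	Varicose veins of lower extremities
J32	Chronic sinusitis
J44	Other chronic obstructive pulmonary disease
J45	Asthma
J96	Respiratory failure
K21	Gastro-oesophageal reflux disease
K25	Gastric ulcer
K27	Peptic ulcer
K29	Gastritis and duodenitis
K31	Other diseases of stomach and duodenum
K72	Hepatic failure
K74	Fibrosis and cirrhosis of liver
K76	Other diseases of liver
K80	Cholelithiasis
K83	Other diseases of biliary tract
M10	Gout
M17	Gonarthrosis
M47	Spondylosis
M48	Other spondylopathies
M50	Cervical disc disorders
M51	Other intervertebral disc disorders
M81	Osteoporosis without pathological fracture
N18	Chronic kidney disease
N19	Unspecified kidney failure
N28	Other disorders of kidney and ureter
N40	Hyperplasia of prostate
N95	Menopausal and other perimenopausal disorders
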