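concept_id	preferred_term	synonyms	housing_related
H0001	Homelessness	homeless|homeless person	1
H0002	Unstable housing	housing instability|unstable housing situation	1
H0003	Housing insecurity	housing insecure	1
H0004	Inadequate housing	poor housing conditions|substandard housing	1
H0005	Lives in shelter	living in shelter|shelter resident|lives in a shelter	1
H0006	Transient living arrangement	transient housing	1
H0007	Housing problem	housing issues|housing problems|problem with housing	1
H0008	Emergency shelter placement	emergency housing	1
H0009	Eviction from home	evicted|eviction	1
H0010	Unsheltered person	living on the streets|street dwelling|sleeping outside	1
H0011	At risk of homelessness	risk of homelessness	1
H0012	Chronic homelessness	chronically homeless	1
C0001	Diabetes mellitus	DM|diabetes	0
C0002	Essential hypertension	HTN|high blood pressure|hypertension	0
C0003	Asthma	bronchial asthma	0
C0004	Chronic obstructive pulmonary disease	COPD	0
C0005	Major depressive disorder	depression|MDD	0
C0006	Generalized anxiety disorder	anxiety|GAD	0
C0007	Opioid use disorder	OUD|opioid dependence	0
C0008	Stimulant use disorder	stimulant dependence	0
C0009	Cocaine use disorder	cocaine dependence	0
C0010	Alcohol use disorder	AUD|alcohol dependence	0
C0011	Hepatitis C	HCV|hep c	0
C0012	Human immunodeficiency virus infection	HIV	0
C0013	Pneumonia	community acquired pneumonia	0
C0014	Cellulitis	skin infection	0
C0015	Sepsis	septicemia	0
C0016	Acute kidney injury	AKI|acute renal failure	0
C0017	Chronic kidney disease	CKD	0
C0018	Congestive heart failure	CHF|heart failure	0
C0019	Atrial fibrillation	afib	0
C0020	Myocardial infarction	MI|heart attack	0
C0021	Stroke	cerebrovascular accident|CVA	0
C0022	Seizure disorder	epilepsy	0
C0023	Migraine	migraine headache	0
C0024	Gastroesophageal reflux disease	GERD|acid reflux	0
C0025	Peptic ulcer disease	PUD	0
C0026	Cirrhosis of liver	cirrhosis	0
C0027	Pancreatitis	acute pancreatitis	0
C0028	Anemia	low hemoglobin	0
C0029	Thrombocytopenia	low platelets	0
C0030	Deep vein thrombosis	DVT	0
C0031	Pulmonary embolism	PE	0
C0032	Osteoarthritis	OA|degenerative joint disease	0
C0033	Rheumatoid arthritis	RA	0
C0034	Low back pain	lumbago	0
C0035	Fracture of femur	femur fracture	0
C0036	Traumatic brain injury	TBI|head injury	0
C0037	Post-traumatic stress disorder	PTSD	0
C0038	Bipolar disorder	bipolar affective disorder	0
C0039	Schizophrenia	schizoaffective disorder	0
C0040	Suicidal ideation	SI	0
C0041	Tobacco use disorder	nicotine dependence|smoker	0
C0042	Obesity	morbid obesity	0
C0043	Malnutrition	undernutrition	0
C0044	Dehydration	volume depletion	0
C0045	Hyponatremia	low sodium	0
C0046	Hypokalemia	low potassium	0
C0047	Urinary tract infection	UTI	0
C0048	Constipation	obstipation	0
C0049	Diarrhea	loose stools	0
C0050	Nausea and vomiting	emesis	0
C0051	Abdominal pain	stomach pain	0
C0052	Chest pain	angina	0
C0053	Shortness of breath	dyspnea|SOB	0
C0054	Cough	productive cough	0
C0055	Fever	pyrexia	0
C0056	Headache	cephalgia	0
C0057	Dizziness	vertigo	0
C0058	Syncope	fainting	0
C0059	Fatigue	tiredness	0
C0060	Insomnia	sleeplessness	0
C0061	Wound infection	infected wound	0
C0062	Abscess	skin abscess	0
C0063	Endocarditis	infective endocarditis	0
C0064	Osteomyelitis	bone infection	0
C0065	Overdose	drug overdose	0
C0066	Opioid overdose	heroin overdose	0
C0067	Withdrawal syndrome	drug withdrawal	0
C0068	Naloxone administration	narcan given	0
C0069	Methadone maintenance	methadone treatment	0
C0070	Buprenorphine treatment	suboxone treatment	0
C0071	Intravenous drug use	IVDU|IV drug use	0
C0072	Hepatitis B	HBV	0
C0073	Tuberculosis	TB	0
C0074	Influenza	flu	0
C0075	COVID-19	coronavirus infection	0
C0076	Hyperlipidemia	high cholesterol	0
C0077	Hypothyroidism	low thyroid	0
C0078	Hyperthyroidism	overactive thyroid	0
C0079	Gout	gouty arthritis	0
C0080	Psoriasis	plaque psoriasis	0
C0081	Eczema	atopic dermatitis	0
C0082	Conjunctivitis	pink eye	0
C0083	Otitis media	ear infection	0
C0084	Pharyngitis	sore throat|strep throat	0
C0085	Sinusitis	sinus infection	0
C0086	Bronchitis	acute bronchitis	0
C0087	Allergic rhinitis	hay fever	0
C0088	Dental caries	tooth decay	0
C0089	Pregnancy	intrauterine pregnancy	0
C0090	Food insecurity	lack of food	0
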