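pt	soc
Dyskinesia	Nervous system disorders
Dystonia	Nervous system disorders
Tardive dyskinesia	Nervous system disorders
Hyperkinesia	Nervous system disorders
Ballismus	Nervous system disorders
Alien limb syndrome	Nervous system disorders
On and off phenomenon	Nervous system disorders
Freezing phenomenon	Nervous system disorders
Tremor	Nervous system disorders
Bradykinesia	Nervous system disorders
Headache	Nervous system disorders
Dizziness	Nervous system disorders
Somnolence	Nervous system disorders
Parkinson's disease	Nervous system disorders
Parkinsonism	Nervous system disorders
Cogwheel rigidity	Nervous system disorders
Balance disorder	Nervous system disorders
Syncope	Nervous system disorders
Seizure	Nervous system disorders
Paraesthesia	Nervous system disorders
Memory impairment	Nervous system disorders
Dysarthria	Nervous system disorders
Akinesia	Nervous system disorders
Therapeutic response shortened	General disorders and administration site conditions
Therapeutic response incomplete	General disorders and administration site conditions
Therapeutic response decreased	General disorders and administration site conditions
Drug ineffective	General disorders and administration site conditions
Fatigue	General disorders and administration site conditions
Asthenia	General disorders and administration site conditions
Gait disturbance	General disorders and administration site conditions
Oedema peripheral	General disorders and administration site conditions
Pyrexia	General disorders and administration site conditions
Malaise	General disorders and administration site conditions
Condition aggravated	General disorders and administration site conditions
Feeling abnormal	General disorders and administration site conditions
Drug interaction	General disorders and administration site conditions
Death	General disorders and administration site conditions
Hallucination	Psychiatric disorders
Hallucination, visual	Psychiatric disorders
Confusional state	Psychiatric disorders
Dementia	Psychiatric disorders
Psychotic disorder	Psychiatric disorders
Insomnia	Psychiatric disorders
Anxiety	Psychiatric disorders
Depression	Psychiatric disorders
Agitation	Psychiatric disorders
Impulse-control disorder	Psychiatric disorders
Nausea	Gastrointestinal disorders
Vomiting	Gastrointestinal disorders
Constipation	Gastrointestinal disorders
Diarrhoea	Gastrointestinal disorders
Abdominal pain	Gastrointestinal disorders
Dysphagia	Gastrointestinal disorders
Dry mouth	Gastrointestinal disorders
Palpitations	Cardiac disorders
Hypotension	Vascular disorders
Orthostatic hypotension	Vascular disorders
Hypertension	Vascular disorders
Urinary tract infection	Infections and infestations
Pneumonia	Infections and infestations
Muscle spasms	Musculoskeletal and connective tissue disorders
Arthralgia	Musculoskeletal and connective tissue disorders
Back pain	Musculoskeletal and connective tissue disorders
Fall	Injury, poisoning and procedural complications
Rash	Skin and subcutaneous tissue disorders
Hyperhidrosis	Skin and subcutaneous tissue disorders
Acute kidney injury	Renal and urinary disorders
Dyspnoea	Respiratory, thoracic and mediastinal disorders
Decreased appetite	Metabolism and nutrition disorders
Weight decreased	Investigations
Blood pressure decreased	Investigations
Vision blurred	Eye disorders
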