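pt,soc
Off label use,"Injury, poisoning and procedural complications"
Product dose omission issue,"Injury, poisoning and procedural complications"
Incorrect dose administered,"Injury, poisoning and procedural complications"
Accidental exposure to product,"Injury, poisoning and procedural complications"
Infusion related reaction,"Injury, poisoning and procedural complications"
Drug ineffective,General disorders and administration site conditions
Fatigue,General disorders and administration site conditions
Injection site pain,General disorders and administration site conditions
Condition aggravated,General disorders and administration site conditions
Pyrexia,General disorders and administration site conditions
Diarrhoea,Gastrointestinal disorders
Abdominal pain,Gastrointestinal disorders
Nausea,Gastrointestinal disorders
Vomiting,Gastrointestinal disorders
Haematochezia,Gastrointestinal disorders
Intestinal obstruction,Gastrointestinal disorders
Frequent bowel movements,Gastrointestinal disorders
Fistula,Gastrointestinal disorders
Intestinal stenosis,Gastrointestinal disorders
Nasopharyngitis,Infections and infestations
Upper respiratory tract infection,Infections and infestations
Lower respiratory tract infection,Infections and infestations
Cellulitis,Infections and infestations
Abscess,Infections and infestations
Clostridium difficile infection,Infections and infestations
Kidney infection,Infections and infestations
Gastrointestinal infection,Infections and infestations
Postoperative wound infection,Infections and infestations
Anal abscess,Infections and infestations
Headache,Nervous system disorders
Dizziness,Nervous system disorders
Migraine,Nervous system disorders
Rash,Skin and subcutaneous tissue disorders
Pruritus,Skin and subcutaneous tissue disorders
Alopecia,Skin and subcutaneous tissue disorders
Psoriasis,Skin and subcutaneous tissue disorders
Arthralgia,Musculoskeletal and connective tissue disorders
Back pain,Musculoskeletal and connective tissue disorders
Myalgia,Musculoskeletal and connective tissue disorders
Palpitations,Cardiac disorders
Myocardial infarction,Cardiac disorders
Cardiac failure,Cardiac disorders
Cough,"Respiratory, thoracic and mediastinal disorders"
Dyspnoea,"Respiratory, thoracic and mediastinal disorders"
Skin cancer,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Basal cell carcinoma,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Lymphoma,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Cholelithiasis,Hepatobiliary disorders
Cholangitis,Hepatobiliary disorders
Weight decreased,Investigations
Drug level decreased,Investigations
Faecal calprotectin increased,Investigations
Anxiety,Psychiatric disorders
Depression,Psychiatric disorders
Hypertension,Vascular disorders
Deep vein thrombosis,Vascular disorders
Vision blurred,Eye disorders
Nephrolithiasis,Renal and urinary disorders
Anaemia,Blood and lymphatic system disorders
Hypersensitivity,Immune system disorders
Decreased appetite,Metabolism and nutrition disorders
Crohns disease,Gastrointestinal disorders
Abdominal abscess,Infections and infestations
Rectal abscess,Infections and infestations
Abscess intestinal,Infections and infestations
Infected fistula,Infections and infestations
Postoperative abscess,Infections and infestations
Perineal abscess,Infections and infestations
Spirochaetal infection,Infections and infestations
Transitional cell carcinoma recurrent,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Small intestine adenocarcinoma,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Choroid melanoma,"Neoplasms benign, malignant and unspecified (incl cysts and polyps)"
Congenital pulmonary airway malformation,"Congenital, familial and genetic disorders"
Product storage error,"Injury, poisoning and procedural complications"
Anastomotic stenosis,"Injury, poisoning and procedural complications"
Jejunal stenosis,Gastrointestinal disorders
Fecal calprotectin increased,Investigations
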