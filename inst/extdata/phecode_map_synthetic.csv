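icd9,phecode,description,category,exclusion_lo,exclusion_hi,sex
278.02,278.0,Overweight,endocrine/metabolic,278,278.99,none
278.00,278.1,Obesity,endocrine/metabolic,278,278.99,none
278.03,278.1,Obesity,endocrine/metabolic,278,278.99,none
278.01,278.11,Morbid obesity,endocrine/metabolic,278,278.99,none
250.00,250.2,Type 2 diabetes,endocrine/metabolic,249,250.99,none
250.60,250.2,Type 2 diabetes,endocrine/metabolic,249,250.99,none
272.00,272.1,Hyperlipidemia,endocrine/metabolic,272,272.99,none
272.40,272.1,Hyperlipidemia,endocrine/metabolic,272,272.99,none
327.23,327.3,Sleep apnea,neurological,327,327.99,none
780.57,327.3,Sleep apnea,neurological,327,327.99,none
610.10,610.1,Fibrocystic breast disease,genitourinary,610,611.99,female
610.20,610.1,Fibrocystic breast disease,genitourinary,610,611.99,female
622.80,622.1,Non-inflammatory disorders of cervix,genitourinary,622,622.99,female
571.80,571.8,Chronic nonalcoholic liver disease,digestive,571,571.99,none
530.81,530.11,GERD,digestive,530,530.99,none
041.10,041.1,Staphylococcus infection,infectious diseases,038,041.99,none
041.11,041.1,Staphylococcus infection,infectious diseases,038,041.99,none
041.00,041.0,Streptococcus infection,infectious diseases,038,041.99,none
041.01,041.0,Streptococcus infection,infectious diseases,038,041.99,none
481.00,480.1,Pneumococcal pneumonia,respiratory,480,488.99,none
038.00,038.2,Gram positive septicemia,infectious diseases,038,038.99,none
038.20,038.2,Gram positive septicemia,infectious diseases,038,038.99,none
401.10,401.1,Essential hypertension,circulatory system,401,405.99,none
401.90,401.1,Essential hypertension,circulatory system,401,405.99,none
584.90,585.1,Acute renal failure,genitourinary,585,585.99,none
707.10,707.1,Chronic ulcer of leg or foot,dermatologic,707,707.99,none
682.90,681.1,Superficial cellulitis and abscess,dermatologic,681,682.99,none
730.00,710.1,Osteomyelitis,musculoskeletal,710,710.99,none
719.00,719.1,Joint effusion,musculoskeletal,719,719.99,none
729.50,729.5,Pain in limb,musculoskeletal,729.5,729.5,none
780.79,780.7,Malaise and fatigue,symptoms,780.7,780.7,none
780.71,780.7,Malaise and fatigue,symptoms,780.7,780.7,none
523.40,523.3,Chronic periodontitis,digestive,523,523.99,none
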