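"product_name","dosage_form","atc","components"
"Acetylsalicylic acid 100mg HSP","tablet","B01AC06","acetylsalicylic acid:100 mg"
"Tamsulosin 0.4mg HSP","retard-capsule","G04CA02","tamsulosin:0.4 mg"
"Amlodipine 5mg HSP","tablet","C08CA01","amlodipine:5 mg"
"Metoprolol succinate 95mg HSP","retard-tablet","C07AB02","metoprolol|succinate:95 mg"
"Atorvastatin 40mg HSP","tablet","C10AA05","atorvastatin:40 mg"
"Ramipril 5mg HSP","tablet","C09AA05","ramipril:5 mg"
"L-thyroxine 0.1mg HSP","tablet","H03AA01","l-thyroxine:0.1 mg"
"Colecalciferol 1000iu HSP","tablet","A11CC05","colecalciferol:1000 iu"
"Simvastatin 40mg HSP","tablet","C10AA01","simvastatin:40 mg"
"Torasemide 10mg HSP","tablet","C03CA04","torasemide:10 mg"
"Candesartan 16mg HSP","tablet","C09CA06","candesartan:16 mg"
"Dipyrone 500mg HSP","tablet","N02BB02","dipyrone:500 mg"
"Pantoprazole 40mg HSP","tablet","A02BC02","pantoprazole:40 mg"
"Metformin 1000mg HSP","tablet","A10BA02","metformin:1000 mg"
"Bisoprolol 5mg HSP","tablet","C07AB07","bisoprolol:5 mg"
"Rosuvastatin 20mg HSP","tablet","C10AA07","rosuvastatin:20 mg"
"Allopurinol 300mg HSP","tablet","M04AA01","allopurinol:300 mg"
"Ibuprofen 600mg HSP","tablet","M01AE01","ibuprofen:600 mg"
"Apixaban 5mg HSP","tablet","B01AF02","apixaban:5 mg"
"Rivaroxaban 20mg HSP","tablet","B01AF01","rivaroxaban:20 mg"
"Hydrochlorothiazide 12.5mg HSP","tablet","C03AA03","hydrochlorothiazide:12.5 mg"
"Salbutamol 0.1mg HSP","inhaler","R03AC02","salbutamol:0.1 mg"
"Insulin glargine 100iu/ml HSP","pen","A10AE04","insulin glargine:100 iu/ml"
"Empagliflozin 10mg HSP","tablet","A10BK03","empagliflozin:10 mg"
"Candesartan 32mg HSP","tablet","C09CA06","candesartan:32 mg"
"Hydrochlorothiazide 25mg HSP","tablet","C03AA03","hydrochlorothiazide:25 mg"
"Enalapril 10mg HSP","tablet","C09AA02","enalapril:10 mg"
"Sitagliptin 50mg HSP","tablet","A10BH01","sitagliptin:50 mg"
"Valsartan 160mg HSP","tablet","C09CA03","valsartan:160 mg"
"Indapamide 1.5mg HSP","tablet","C03BA11","indapamide:1.5 mg"
"Indapamide 2.5mg HSP","tablet","C03BA11","indapamide:2.5 mg"
"Nebivolol 5mg HSP","tablet","C07AB12","nebivolol:5 mg"
"Perindopril 8mg HSP","tablet","C09AA04","perindopril:8 mg"
"Lercanidipine 10mg HSP","tablet","C08CA13","lercanidipine:10 mg"
"Telmisartan 80mg HSP","tablet","C09CA07","telmisartan:80 mg"
"Chlortalidone 12.5mg HSP","tablet","C03BA04","chlortalidone:12.5 mg"
"Felodipine 5mg HSP","tablet","C08CA02","felodipine:5 mg"
"Thiamine 100mg HSP","tablet","A11DA01","thiamine:100 mg"
"Pyridoxine 50mg HSP","tablet","A11HA02","pyridoxine:50 mg"
"Cyanocobalamin 1mg HSP","tablet","B03BA01","cyanocobalamin:1 mg"
"Folic acid 5mg HSP","tablet","B03BB01","folic acid:5 mg"
"Clopidogrel 75mg HSP","tablet","B01AC04","clopidogrel:75 mg"
"Sertraline 50mg HSP","tablet","N06AB06","sertraline:50 mg"
"Lisinopril 10mg HSP","tablet","C09AA03","lisinopril:10 mg"
"Losartan 50mg HSP","tablet","C09CA01","losartan:50 mg"
"Carvedilol 12.5mg HSP","tablet","C07AG02","carvedilol:12.5 mg"
"Furosemide 40mg HSP","tablet","C03CA01","furosemide:40 mg"
"Spironolactone 25mg HSP","tablet","C03DA01","spironolactone:25 mg"
"Gabapentin 300mg HSP","tablet","N03AX12","gabapentin:300 mg"
"Pregabalin 75mg HSP","capsule","N03AX16","pregabalin:75 mg"
"Levetiracetam 500mg HSP","tablet","N03AX14","levetiracetam:500 mg"
"Paracetamol 500mg HSP","tablet","N02BE01","paracetamol:500 mg"
"Enoxaparin 40mg HSP","syringe","B01AB05","enoxaparin:40 mg"
"Ondansetron 8mg HSP","tablet","A04AA01","ondansetron:8 mg"
"Macrogol 13g HSP","sachet","A06AD15","macrogol:13 g"
"Cetirizine 10mg HSP","tablet","R06AE07","cetirizine:10 mg"
"Amoxicillin 500mg HSP","tablet","J01CA04","amoxicillin:500 mg"
"Prednisolone 5mg HSP","tablet","H02AB06","prednisolone:5 mg"
"Simeticone 80mg HSP","tablet","A03AX13","simeticone:80 mg"
"Budesonide 0.2mg HSP","inhaler","R03BA02","budesonide:0.2 mg"
"Ezetimib-Simva 10/40 HSP","tablet","C10BA02","ezetimibe:10 mg;simvastatin:40 mg"
"Candesartan-HCT 16/12.5 HSP","tablet","C09DA06","candesartan:16 mg;hydrochlorothiazide:12.5 mg"
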