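system,code,is_prefix,label,treatment_group,cancer_type,role
ICD10GM,C33,TRUE,Malignant neoplasm of trachea,none,none,lc_diagnosis
ICD10GM,C34,TRUE,Malignant neoplasm of bronchus and lung,none,none,lc_diagnosis
ICD10GM,C77,TRUE,Secondary and unspecified malignant neoplasm of lymph nodes,none,none,lymph_met
ICD10GM,C78,TRUE,Secondary malignant neoplasm of respiratory and digestive organs,none,none,distant_met
ICD10GM,C79,TRUE,Secondary malignant neoplasm of other sites,none,none,distant_met
ATC,L01XC06,FALSE,Cetuximab,Immunotherapy,NSCLC,therapy
ATC,L01XC07,FALSE,Bevacizumab,Immunotherapy,NSCLC,therapy
ATC,L01XC11,FALSE,Ipilimumab,Immunotherapy,NSCLC,therapy
ATC,L01XC17,FALSE,Nivolumab,Immunotherapy,NSCLC,therapy
ATC,L01XC18,FALSE,Pembrolizumab,Immunotherapy,NSCLC,therapy
ATC,L01XC22,FALSE,Necitumumab,Immunotherapy,NSCLC,therapy
ATC,L01XC28,FALSE,Durvalumab,Immunotherapy,NSCLC,therapy
ATC,L01XC31,FALSE,Avelumab,Immunotherapy,NSCLC,therapy
ATC,L01XC32,FALSE,Atezolizumab,Immunotherapy,NSCLC,therapy
OPS,6-001.a,FALSE,Cetuximab administration,Immunotherapy,NSCLC,therapy
OPS,6-002.9,FALSE,Bevacizumab administration,Immunotherapy,NSCLC,therapy
OPS,6-006.h,FALSE,Ipilimumab administration,Immunotherapy,NSCLC,therapy
OPS,6-008.m,FALSE,Nivolumab administration,Immunotherapy,NSCLC,therapy
OPS,6-009.3,FALSE,Pembrolizumab administration,Immunotherapy,NSCLC,therapy
OPS,6-009.g,FALSE,Necitumumab administration,Immunotherapy,NSCLC,therapy
OPS,8-547,TRUE,Other immunotherapies,Immunotherapy,none,therapy
ATC,L01XE02,FALSE,Gefitinib,Inhibitors,NSCLC,therapy
ATC,L01XE03,FALSE,Erlotinib,Inhibitors,NSCLC,therapy
ATC,L01XE13,FALSE,Afatinib,Inhibitors,NSCLC,therapy
ATC,L01XE16,FALSE,Crizotinib,Inhibitors,NSCLC,therapy
ATC,L01XE23,FALSE,Dabrafenib,Inhibitors,NSCLC,therapy
ATC,L01XE25,FALSE,Trametinib,Inhibitors,NSCLC,therapy
ATC,L01XE28,FALSE,Ceritinib,Inhibitors,NSCLC,therapy
ATC,L01XE31,FALSE,Nintedanib,Inhibitors,NSCLC,therapy
ATC,L01XE35,FALSE,Osimertinib,Inhibitors,NSCLC,therapy
OPS,6-006.c,FALSE,Crizotinib administration,Inhibitors,NSCLC,therapy
OPS,6-007.5,FALSE,Dabrafenib administration,Inhibitors,NSCLC,therapy
OPS,6-009.7,FALSE,Trametinib administration,Inhibitors,NSCLC,therapy
OPS,6-008.a,FALSE,Ceritinib administration,Inhibitors,NSCLC,therapy
ATC,L01AA01,FALSE,Cyclophosphamide,Chemotherapy,SCLC,therapy
ATC,L01AA06,FALSE,Ifosfamide,Chemotherapy,SCLC,therapy
ATC,L01AA07,FALSE,Trofosfamide,Chemotherapy,SCLC,therapy
ATC,L01AD02,FALSE,Lomustine,Chemotherapy,SCLC,therapy
ATC,L01AX03,FALSE,Temozolomide,Chemotherapy,none,therapy
ATC,L01BA04,FALSE,Pemetrexed,Chemotherapy,NSCLC,therapy
ATC,L01BC02,FALSE,5-Fluorouracil,Chemotherapy,NSCLC,therapy
ATC,L01BC05,FALSE,Gemcitabine,Chemotherapy,NSCLC,therapy
ATC,L01BC06,FALSE,Capecitabine,Chemotherapy,none,therapy
ATC,L01CA04,FALSE,Vinorelbine,Chemotherapy,NSCLC,therapy
ATC,L01CB01,FALSE,Etoposide,Chemotherapy,SCLC,therapy
ATC,L01CD01,FALSE,Paclitaxel incl. nab-paclitaxel,Chemotherapy,NSCLC,therapy
ATC,L01CD02,FALSE,Docetaxel,Chemotherapy,none,therapy
ATC,L01DB01,FALSE,Doxorubicin,Chemotherapy,SCLC,therapy
ATC,L01DB03,FALSE,Epirubicin,Chemotherapy,SCLC,therapy
ATC,L01DC03,FALSE,Mitomycin,Chemotherapy,NSCLC,therapy
ATC,L01XA01,FALSE,Cisplatin,Chemotherapy,none,therapy
ATC,L01XA02,FALSE,Carboplatin,Chemotherapy,SCLC,therapy
ATC,L01XA03,FALSE,Oxaliplatin,Chemotherapy,none,therapy
ATC,L01XX17,FALSE,Topotecan,Chemotherapy,SCLC,therapy
ATC,L01XX19,FALSE,Irinotecan incl. liposomal irinotecan,Chemotherapy,SCLC,therapy
ATC,V03AF03,FALSE,Calcium folinate (folic acid),Chemotherapy,NSCLC,therapy
OPS,6-002.e,FALSE,Temozolomide administration,Chemotherapy,none,therapy
OPS,6-005.c,FALSE,Temozolomide administration (alt.),Chemotherapy,none,therapy
OPS,6-001.c,FALSE,Pemetrexed administration,Chemotherapy,NSCLC,therapy
OPS,6-001.1,FALSE,Gemcitabine administration,Chemotherapy,NSCLC,therapy
OPS,6-005.d,FALSE,Nab-paclitaxel administration,Chemotherapy,NSCLC,therapy
OPS,6-001.f,FALSE,Paclitaxel administration,Chemotherapy,NSCLC,therapy
OPS,6-002.h,FALSE,Docetaxel administration,Chemotherapy,none,therapy
OPS,6-001.b,FALSE,Doxorubicin administration,Chemotherapy,SCLC,therapy
OPS,6-002.8,FALSE,Doxorubicin administration (alt.),Chemotherapy,SCLC,therapy
OPS,6-002.4,FALSE,Topotecan administration,Chemotherapy,SCLC,therapy
OPS,6-001.3,FALSE,Irinotecan administration,Chemotherapy,SCLC,therapy
OPS,6-009.e,FALSE,Liposomal irinotecan administration,Chemotherapy,SCLC,therapy
OPS,8-542,TRUE,Non-complex chemotherapy,Chemotherapy,none,therapy
OPS,8-543,TRUE,Moderately complex and intensive chemotherapy cycle,Chemotherapy,none,therapy
OPS,8-544,TRUE,Highly complex and intensive chemotherapy cycle,Chemotherapy,none,therapy
OPS,8-546,TRUE,Hyperthermic chemotherapy,Chemotherapy,none,therapy
OPS,8-549,TRUE,Percutaneous closed organ perfusion with chemotherapeutic agents,Chemotherapy,none,therapy
OPS,8-52,TRUE,Inpatient radiotherapy,Radiotherapy,none,therapy
EBM,25320,FALSE,High-voltage therapy,Radiotherapy,none,therapy
EBM,25321,FALSE,High-voltage therapy,Radiotherapy,none,therapy
EBM,25322,FALSE,High-voltage therapy,Radiotherapy,none,therapy
EBM,25323,FALSE,High-voltage therapy,Radiotherapy,none,therapy
EBM,25331,FALSE,Brachytherapy,Radiotherapy,none,therapy
EBM,25333,FALSE,Brachytherapy,Radiotherapy,none,therapy
EBM,25340,FALSE,Radiotherapy planning,Radiotherapy,none,therapy
EBM,25341,FALSE,Radiotherapy planning,Radiotherapy,none,therapy
EBM,25342,FALSE,Radiotherapy planning,Radiotherapy,none,therapy
EBM,13461,FALSE,Study-context pneumology service (primary),Study,none,study_marker
EBM,13492,FALSE,Study-context pneumology service (primary),Study,none,study_marker
EBM,13494,FALSE,Study-context pneumology service (primary),Study,none,study_marker
EBM,02100,FALSE,Infusion at least 10 min (study companion),none,none,study_marker
EBM,02101,FALSE,Infusion at least 60 min (study companion),none,none,study_marker
EBM,01510,FALSE,Observation and care 2 h (study companion),none,none,study_marker
EBM,01511,FALSE,Observation and care 4 h (study companion),none,none,study_marker
EBM,01512,FALSE,Observation and care 6 h (study companion),none,none,study_marker
OPS,8-541,TRUE,Inpatient application of medication (other-treatment marker),none,none,inpatient_chemo_marker
EBM,19320,FALSE,Biomarker testing,none,none,biomarker
EBM,19321,FALSE,Biomarker testing,none,none,biomarker
EBM,19322,FALSE,Biomarker testing,none,none,biomarker
OPS,1-991,TRUE,Biomarker testing key,none,none,biomarker
OPS,1-992,TRUE,Biomarker testing key,none,none,biomarker
OPS,1-690.0,FALSE,Diagnostic bronchoscopy,none,none,bronchoscopy
OPS,1-690.1,FALSE,Diagnostic bronchoscopy,none,none,bronchoscopy
OPS,1-620,TRUE,Diagnostic tracheobronchoscopy,none,none,bronchoscopy
EBM,09315,FALSE,Bronchoscopy,none,none,bronchoscopy
EBM,13662,FALSE,Bronchoscopy,none,none,bronchoscopy
OPS,5-320,TRUE,Lung excision (synthetic placeholder surgery set),none,none,surgery
OPS,5-321,TRUE,Lung segment resection (synthetic placeholder surgery set),none,none,surgery
OPS,5-322,TRUE,Lobectomy (synthetic placeholder surgery set),none,none,surgery
OPS,5-323,TRUE,Bilobectomy (synthetic placeholder surgery set),none,none,surgery
OPS,5-324,TRUE,Pneumonectomy (synthetic placeholder surgery set),none,none,surgery
OPS,5-325,TRUE,Extended lung resection (synthetic placeholder surgery set),none,none,surgery
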