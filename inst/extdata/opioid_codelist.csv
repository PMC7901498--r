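code_id,terminology,description,category,source
OPI001,READ,Heroin dependence,CLINICAL_DEFINITE,bundled illustrative list
OPI002,READ,Opioid dependence syndrome,CLINICAL_DEFINITE,bundled illustrative list
OPI003,READ,Opiate misuse,CLINICAL_DEFINITE,bundled illustrative list
OPI004,READ,Accidental heroin overdose,CLINICAL_DEFINITE,bundled illustrative list
INJ001,READ,Injecting drug user,CLINICAL_PROBABLE,bundled illustrative list
MIS001,READ,Misuse of codeine tablets,CLINICAL_PROBABLE,bundled illustrative list
OAT-METH-1MG-ML,PRODUCT,Methadone 1mg/ml oral solution sugar free,OAT_PRODUCT,bundled illustrative list
OAT-BUP-8MG-TAB,PRODUCT,Buprenorphine 8mg sublingual tablet,OAT_PRODUCT,bundled illustrative list
ANL-BUP-PATCH,PRODUCT,Buprenorphine 5micrograms/hour transdermal patch,EXCLUDED,bundled illustrative list
XRX001,READ,"Adverse reaction to methadone, indication unclear",EXCLUDED,bundled illustrative list
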