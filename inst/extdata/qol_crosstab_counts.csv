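variable,level,poor,good
age_group,<=55,138,452
age_group,56-65,675,1435
age_group,66-75,1005,1371
age_group,76-85,88,74
hospital_location,Metro,1309,2387
hospital_location,Regional,597,945
institution,Public,626,799
institution,Private,1280,2533
psa,<=10,1384,2674
psa,10.1-20.0,333,386
psa,>20,189,272
nccn,Low risk,74,220
nccn,Intermediate risk,1165,2326
nccn,High risk,476,559
nccn,Very high risk/Metastatic,191,227
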