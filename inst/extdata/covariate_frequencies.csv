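covariate,level,prob,scope
age_group,<=55,0.1126,individual
age_group,56-65,0.4028,individual
age_group,66-75,0.4537,individual
age_group,76-85,0.0309,individual
nccn,Low risk,0.0561,individual
nccn,Intermediate risk,0.6665,individual
nccn,High risk,0.1976,individual
nccn,Very high risk/Metastatic,0.0798,individual
psa,<=10,0.7747,individual
psa,10.1-20.0,0.1373,individual
psa,>20,0.0880,individual
institution,Private,0.7279,individual
institution,Public,0.2721,individual
hospital_location,Metro,0.7056,individual
hospital_location,Regional,0.2944,individual
isup,ISUP1,0.0872,individual
isup,ISUP2,0.4740,individual
isup,ISUP3,0.2197,individual
isup,ISUP4/ISUP5,0.2191,individual
t_stage,T1,0.4137,individual
t_stage,T2,0.2442,individual
t_stage,T3/T4,0.0382,individual
t_stage,Unknown,0.3039,individual
year,2015,0.1430,year
year,2016,0.1642,year
year,2017,0.1745,year
year,2018,0.1660,year
year,2019,0.1537,year
year,2020,0.1386,year
year,2021,0.0600,year
irsd_quartile,Q1,0.2532,area
irsd_quartile,Q2,0.2785,area
irsd_quartile,Q3,0.2278,area
irsd_quartile,Q4,0.2405,area
remoteness,Accessible,0.2278,area
remoteness,Moderately accessible,0.0886,area
remoteness,Highly accessible,0.6836,area
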