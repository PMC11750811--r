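proband,sex,age_years,ethnicity,consanguinity,sars_cov2_evidence,gi_symptoms,rash,neuro,myocarditis,coronary_involvement,kawasaki,misc_dx,icu
P1,male,7,Kuwaiti,0,1,1,1,0,0,1,0,1,0
P2,male,2.7,Kuwaiti,0,0,0,0,0,0,0,0,0,0
P3,male,0.7,Kuwaiti,1,1,1,1,0,0,0,0,1,1
P4,male,7.8,Kuwaiti,0,1,1,1,0,0,1,0,1,1
P5,male,3.7,Kuwaiti,0,1,1,1,1,1,0,0,1,1
P6,male,6.8,Kuwaiti,1,1,1,1,0,0,0,0,1,0
P7,female,12.8,Kuwaiti,0,1,1,1,0,0,0,0,1,0
P8,male,8.2,Kuwaiti,0,1,1,1,0,0,1,0,1,0
P9,male,12.5,Kuwaiti,0,0,0,0,0,0,0,1,0,0
P10,female,5.2,Kuwaiti,0,1,0,0,0,0,0,0,1,0
P11,male,8,Syrian,0,1,0,1,0,0,0,0,1,1
P12,male,7,Syrian,0,1,0,1,0,0,1,0,1,0
P13,male,1.7,Egyptian,0,1,1,1,1,1,0,0,1,1
P14,male,6.6,Egyptian,0,1,0,0,0,0,0,0,0,0
P15,male,12,Egyptian,0,1,0,1,0,0,0,0,1,0
P16,male,9.1,Egyptian,0,1,0,1,0,0,1,0,1,0
P17,male,2.3,Egyptian,0,1,0,1,1,0,0,0,1,0
P18,female,0.5,Egyptian,1,1,1,1,0,0,0,0,1,1
P19,male,12.3,Indian,1,1,1,1,0,0,0,0,1,0
P20,male,10.1,Indian,0,1,1,1,0,0,0,0,1,0
P21,female,7.7,Indian,0,0,1,1,0,NA,0,0,1,1
P22,female,5.3,Indian,0,0,0,0,0,NA,0,1,0,0
P23,male,1.9,SriLankan,0,1,1,1,0,NA,0,0,1,0
P24,female,0.5,Afghan,0,1,0,0,0,0,1,0,1,0
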