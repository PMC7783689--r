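sex,transition,band,family,p1,p2,p3
female,NW-OW,child,lognormal,3.16,1.22,NA
male,NW-OW,child,lognormal,3.27,1.19,NA
female,NW-OW,adolescent,weibull,-5.75,1.85,NA
male,NW-OW,adolescent,weibull,-6.95,2.42,NA
female,NW-OW,adult,loglogistic,1.776927,1,NA
male,NW-OW,adult,loglogistic,1.19706,1,NA
female,OW-OB1,child,lognormal,3.32,1.51,NA
male,OW-OB1,child,lognormal,3.28,1.31,NA
female,OW-OB1,adolescent,weibull,-5.22,1.77,NA
male,OW-OB1,adolescent,weibull,-4.53,1.54,NA
female,OW-OB1,adult,loglogistic,2.602726,1,NA
male,OW-OB1,adult,loglogistic,3.377739,1,NA
female,OB1-OB2,child,lognormal,3.35,1.62,NA
male,OB1-OB2,child,lognormal,3.44,1.62,NA
female,OB1-OB2,adolescent,gompertz,0.12,0.02,NA
male,OB1-OB2,adolescent,gompertz,0.02,0.05,NA
female,OB1-OB2,adult,gompertz,-0.02,0.05,NA
male,OB1-OB2,adult,gompertz,0.01,0.02,NA
female,OW-NW,child,lognormal,1.64,0.95,NA
male,OW-NW,child,lognormal,1.44,0.91,NA
female,OW-NW,adolescent,gompertz,-0.3,0.22,NA
male,OW-NW,adolescent,gompertz,-0.36,0.22,NA
female,OW-NW,adult,gompertz,0.04,0.00141,NA
male,OW-NW,adult,gompertz,0.05,0.00086,NA
female,OB1-OW,child,lognormal,1.28,0.92,NA
male,OB1-OW,child,lognormal,1.26,0.89,NA
female,OB1-OW,adolescent,gompertz,-0.43,0.31,NA
male,OB1-OW,adolescent,gompertz,-0.32,0.16,NA
female,OB1-OW,adult,gompertz,0.03,0.00227,NA
male,OB1-OW,adult,gompertz,0.05,0.0016,NA
female,OB2-OB1,child,lognormal,1.27,0.77,NA
male,OB2-OB1,child,lognormal,1.37,0.84,NA
female,OB2-OB1,adolescent,gompertz,-0.35,0.48,NA
male,OB2-OB1,adolescent,gompertz,-0.16,0.16,NA
female,OB2-OB1,adult,gompertz,0.02,0.00782,NA
male,OB2-OB1,adult,gompertz,0.04,0.00414,NA
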