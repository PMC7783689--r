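state,age_lo,age_hi,hr,hr_lo,hr_hi
NW,2,101,1,1,1
OW,2,65,1.11,1.07,1.15
OW,65,101,1.07,1.03,1.11
OB1,2,65,1.49,1.41,1.57
OB1,65,101,1.3,1.22,1.38
OB2,2,65,2.06,1.88,2.25
OB2,65,101,1.65,1.5,1.81
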