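sex,age,ow,ob1,ob2
female,2,18.09,19.81,21.13
female,3,17.8,19.39,20.55
female,4,17.61,19.1,20.17
female,5,17.51,18.96,19.97
female,6,17.51,18.96,19.97
female,7,17.61,19.1,20.17
female,8,17.8,19.39,20.55
female,9,18.09,19.81,21.13
female,10,18.47,20.38,21.9
female,11,18.95,21.08,22.86
female,12,19.53,21.93,24.02
female,13,20.2,22.92,25.37
female,14,20.97,24.06,26.91
female,15,21.83,25.33,28.64
female,16,22.79,26.74,30.57
female,17,23.85,28.3,32.69
male,2,18.41,20.09,21.6
male,3,18.14,19.68,21.04
male,4,17.95,19.4,20.67
male,5,17.86,19.26,20.48
male,6,17.86,19.26,20.48
male,7,17.95,19.4,20.67
male,8,18.14,19.68,21.04
male,9,18.41,20.09,21.6
male,10,18.78,20.64,22.34
male,11,19.23,21.33,23.28
male,12,19.78,22.15,24.39
male,13,20.42,23.12,25.69
male,14,21.16,24.22,27.18
male,15,21.98,25.46,28.86
male,16,22.89,26.83,30.72
male,17,23.9,28.35,32.77
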