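sex,age,rate
female,0,0.000216871
female,1,0.000218561
female,2,0.000220421
female,3,0.000222468
female,4,0.000224719
female,5,0.000227196
female,6,0.000229921
female,7,0.00023292
female,8,0.000236219
female,9,0.000239848
female,10,0.000243841
female,11,0.000248234
female,12,0.000253068
female,13,0.000258386
female,14,0.000264237
female,15,0.000270674
female,16,0.000277756
female,17,0.000285548
female,18,0.00029412
female,19,0.000303552
female,20,0.000313929
female,21,0.000325346
female,22,0.000337906
female,23,0.000351726
female,24,0.00036693
female,25,0.000383658
female,26,0.000402062
female,27,0.00042231
female,28,0.000444588
female,29,0.000469098
female,30,0.000496064
female,31,0.000525732
female,32,0.000558373
female,33,0.000594285
female,34,0.000633796
female,35,0.000677266
female,36,0.000725092
female,37,0.000777711
female,38,0.000835603
female,39,0.000899296
female,40,0.000969372
female,41,0.00104647
female,42,0.00113129
female,43,0.00122462
female,44,0.00132729
female,45,0.00144026
female,46,0.00156454
female,47,0.00170128
female,48,0.00185172
female,49,0.00201724
female,50,0.00219934
female,51,0.0023997
female,52,0.00262012
female,53,0.00286264
female,54,0.00312946
female,55,0.00342302
female,56,0.003746
female,57,0.00410134
female,58,0.00449228
female,59,0.00492241
female,60,0.00539564
female,61,0.00591629
female,62,0.00648911
female,63,0.00711933
female,64,0.00781271
female,65,0.00857557
female,66,0.00941488
female,67,0.0103383
female,68,0.0113542
female,69,0.012472
female,70,0.0137017
female,71,0.0150547
female,72,0.0165433
female,73,0.0181811
female,74,0.0199829
female,75,0.0219653
female,76,0.0241464
female,77,0.0265461
female,78,0.0291862
female,79,0.0320908
female,80,0.0352866
female,81,0.0388026
female,82,0.0426709
female,83,0.0469269
female,84,0.0516093
female,85,0.056761
female,86,0.0624289
female,87,0.0686648
female,88,0.0755255
female,89,0.0830738
female,90,0.0913785
female,91,0.100515
female,92,0.110568
female,93,0.121628
female,94,0.133796
female,95,0.147183
female,96,0.161912
female,97,0.178117
female,98,0.195946
female,99,0.215562
female,100,0.237143
male,0,0.000222982
male,1,0.000225285
male,2,0.000227819
male,3,0.000230607
male,4,0.000233674
male,5,0.000237048
male,6,0.000240761
male,7,0.000244845
male,8,0.000249339
male,9,0.000254284
male,10,0.000259723
male,11,0.000265708
male,12,0.000272293
male,13,0.000279537
male,14,0.000287507
male,15,0.000296276
male,16,0.000305924
male,17,0.000316538
male,18,0.000328217
male,19,0.000341065
male,20,0.000355201
male,21,0.000370753
male,22,0.000387864
male,23,0.00040669
male,24,0.000427402
male,25,0.00045019
male,26,0.000475261
male,27,0.000502845
male,28,0.000533193
male,29,0.000566581
male,30,0.000603316
male,31,0.000643732
male,32,0.000688198
male,33,0.000737119
male,34,0.000790943
male,35,0.000850161
male,36,0.000915313
male,37,0.000986994
male,38,0.00106586
male,39,0.00115262
male,40,0.00124809
male,41,0.00135311
male,42,0.00146866
male,43,0.0015958
male,44,0.00173567
male,45,0.00188955
male,46,0.00205886
male,47,0.00224514
male,48,0.00245008
male,49,0.00267556
male,50,0.00292363
male,51,0.00319656
male,52,0.00349684
male,53,0.00382721
male,54,0.00419069
male,55,0.0045906
male,56,0.00503057
male,57,0.00551464
male,58,0.00604721
male,59,0.00663316
male,60,0.00727781
male,61,0.00798707
male,62,0.00876741
male,63,0.00962594
male,64,0.0105705
male,65,0.0116097
male,66,0.0127531
male,67,0.014011
male,68,0.015395
male,69,0.0169177
male,70,0.0185929
male,71,0.020436
male,72,0.0224639
male,73,0.0246949
male,74,0.0271495
male,75,0.0298501
male,76,0.0328213
male,77,0.0360902
male,78,0.0396867
male,79,0.0436437
male,80,0.0479971
male,81,0.0527868
male,82,0.0580565
male,83,0.0638542
male,84,0.0702329
male,85,0.0772508
male,86,0.084972
male,87,0.0934669
male,88,0.102813
male,89,0.113096
male,90,0.124409
male,91,0.136856
male,92,0.15055
male,93,0.165616
male,94,0.182192
male,95,0.20043
male,96,0.220494
male,97,0.24257
male,98,0.266858
male,99,0.293579
male,100,0.322978
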