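sex,state,cost
female,NW,0
female,OW,160
female,OB1,631
female,OB2,698
male,NW,0
male,OW,-96
male,OB1,182
male,OB2,1456
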