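dimension,level,decrement
MO,1,0
MO,2,0.05
MO,3,0.10
MO,4,0.15
MO,5,0.20
SC,1,0
SC,2,0.05
SC,3,0.10
SC,4,0.15
SC,5,0.20
UA,1,0
UA,2,0.05
UA,3,0.10
UA,4,0.15
UA,5,0.20
PD,1,0
PD,2,0.05
PD,3,0.10
PD,4,0.15
PD,5,0.20
AD,1,0
AD,2,0.05
AD,3,0.10
AD,4,0.15
AD,5,0.20
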