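dimension,disease,level,count
mo,OI,1,8
mo,OI,2,14
mo,OI,3,10
mo,OI,4,6
mo,OI,5,5
mo,FD,1,18
mo,FD,2,9
mo,FD,3,8
mo,FD,4,7
mo,FD,5,0
mo,XLH,1,3
mo,XLH,2,10
mo,XLH,3,6
mo,XLH,4,2
mo,XLH,5,3
sc,OI,1,26
sc,OI,2,10
sc,OI,3,3
sc,OI,4,2
sc,OI,5,2
sc,FD,1,26
sc,FD,2,11
sc,FD,3,4
sc,FD,4,1
sc,FD,5,0
sc,XLH,1,12
sc,XLH,2,7
sc,XLH,3,1
sc,XLH,4,2
sc,XLH,5,2
ua,OI,1,15
ua,OI,2,13
ua,OI,3,8
ua,OI,4,5
ua,OI,5,2
ua,FD,1,14
ua,FD,2,13
ua,FD,3,8
ua,FD,4,4
ua,FD,5,3
ua,XLH,1,6
ua,XLH,2,10
ua,XLH,3,5
ua,XLH,4,3
ua,XLH,5,0
pd,OI,1,3
pd,OI,2,14
pd,OI,3,19
pd,OI,4,4
pd,OI,5,3
pd,FD,1,1
pd,FD,2,13
pd,FD,3,15
pd,FD,4,9
pd,FD,5,4
pd,XLH,1,2
pd,XLH,2,6
pd,XLH,3,10
pd,XLH,4,5
pd,XLH,5,1
ad,OI,1,17
ad,OI,2,17
ad,OI,3,6
ad,OI,4,3
ad,OI,5,0
ad,FD,1,16
ad,FD,2,12
ad,FD,3,10
ad,FD,4,4
ad,FD,5,0
ad,XLH,1,10
ad,XLH,2,13
ad,XLH,3,1
ad,XLH,4,0
ad,XLH,5,0
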