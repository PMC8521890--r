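truth,LFD,LFU,Falling,Jogging,LS,Sitting,Standing,TRN,Walking
LFD,6274,0,0,0,1221,0,0,113,0
LFU,1156,22769,0,0,10,0,0,177,0
Falling,0,86,374,0,8,0,20,328,4
Jogging,0,0,91,44120,0,0,245,632,2076
LS,0,0,0,0,7324,0,0,13,0
Sitting,0,0,0,0,0,24202,10175,1436,2
Standing,0,0,0,6,0,844,144503,1369,1556
TRN,254,1010,533,78,112,591,5947,30698,2493
Walking,0,0,33,47,0,0,3339,4563,165894
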