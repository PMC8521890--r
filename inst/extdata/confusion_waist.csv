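truth,LFD,LFU,Falling,Jogging,LS,Sitting,Standing,TRN,Walking
LFD,6993,0,0,0,0,0,0,615,0
LFU,1181,21752,0,0,0,0,0,1206,0
Falling,18,66,413,0,22,0,26,252,23
Jogging,0,0,23,44008,0,0,360,306,2467
LS,1471,0,0,0,5664,0,0,202,0
Sitting,0,0,0,0,0,24032,9027,2744,12
Standing,0,0,6,5,0,6756,138157,1833,1548
TRN,543,1065,579,98,64,937,6211,28777,3802
Walking,0,0,17,168,0,10,3696,2690,167295
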