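truth,LFD,LFU,Falling,Jogging,LS,Sitting,Standing,TRN,Walking
LFD,6294,0,0,0,1221,0,0,93,0
LFU,1108,22754,0,0,55,0,0,195,0
Falling,0,87,364,0,3,0,16,323,27
Jogging,0,0,266,43928,0,0,231,932,1807
LS,0,0,0,0,7311,0,0,26,0
Sitting,0,0,0,0,0,2347,33213,242,13
Standing,8,0,0,0,0,2108,142889,1804,1496
TRN,357,1082,642,107,116,10,8135,27138,4399
Walking,0,0,43,28,0,2,3505,11865,158433
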