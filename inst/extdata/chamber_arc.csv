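energy,mu,sense,reading
6 MV,36,CW,6.325
6 MV,1000,CW,176.94
6 MV,36,CCW,6.324
6 MV,1000,CCW,176.82
10 MV,36,CW,5.962
10 MV,1000,CW,166.23
10 MV,36,CCW,5.965
10 MV,1000,CCW,166.12
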