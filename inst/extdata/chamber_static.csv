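energy,mu,reading
6 MV,36,6.361
6 MV,1000,176.70
10 MV,36,5.999
10 MV,1000,166.26
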