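angle,x,y
180,13.06,13.37
90,13.06,13.27
270,13.04,13.27
0,13.06,13.16
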