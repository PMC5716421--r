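angle,reading
0,2.09
90,2.08
180,2.09
270,2.09
arc,2.08
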