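acquisition,kind,picket,position
g270,static,1,-9.16
g270,static,2,-6.06
g270,static,3,-3.01
g270,static,4,0.06
g270,static,5,3.11
g270,static,6,6.16
g270,static,7,9.20
g180,static,1,-9.06
g180,static,2,-5.98
g180,static,3,-2.94
g180,static,4,0.14
g180,static,5,3.16
g180,static,6,6.21
g180,static,7,9.25
g90,static,1,-9.08
g90,static,2,-5.96
g90,static,3,-2.94
g90,static,4,0.14
g90,static,5,3.19
g90,static,6,6.26
g90,static,7,9.31
g0,static,1,-9.16
g0,static,2,-6.06
g0,static,3,-2.99
g0,static,4,0.06
g0,static,5,3.13
g0,static,6,6.21
g0,static,7,9.25
arc356,arc,1,-9.08
arc356,arc,2,-5.98
arc356,arc,3,-2.91
arc356,arc,4,0.19
arc356,arc,5,3.21
arc356,arc,6,6.31
arc356,arc,7,9.36
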