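angle,is_maxflex,n,anterior_flex,anterior_flex_sd,anterior_ext,anterior_ext_sd
100,FALSE,11,-0.6,3.3,-5.0,2.6
105,FALSE,13,-1.3,3.5,-5.4,2.7
110,FALSE,14,-2.0,3.4,-6.3,3.0
115,FALSE,15,-2.6,3.0,-7.0,3.2
120,FALSE,15,-3.5,2.7,-7.5,3.1
125,FALSE,15,-4.6,2.4,-8.1,2.8
130,FALSE,15,-5.8,2.3,-8.9,2.7
135,FALSE,15,-7.0,2.5,-9.5,2.4
140,FALSE,15,-8.2,2.6,-10.0,2.1
145,FALSE,15,-9.4,2.5,-11.0,2.1
150,FALSE,15,-10.9,2.4,-12.1,2.2
155,FALSE,12,-12.3,2.4,-13.4,2.4
161.3,TRUE,12,-14.8,2.9,-14.8,2.9
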