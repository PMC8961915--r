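angle,is_maxflex,n,anterior_flex,anterior_flex_sd,anterior_ext,anterior_ext_sd
100,FALSE,11,-2.7,3.4,2.5,4.4
105,FALSE,13,-1.8,3.9,3.1,4.0
110,FALSE,14,-1.3,4.1,3.7,3.7
115,FALSE,15,-1.2,4.1,4.3,3.5
120,FALSE,15,-0.6,4.3,4.7,3.5
125,FALSE,15,-0.1,4.1,4.9,3.5
130,FALSE,15,0.5,3.8,4.7,3.4
135,FALSE,15,1.0,3.7,4.1,3.1
140,FALSE,15,1.1,3.5,3.0,2.9
145,FALSE,15,0.5,3.0,1.5,2.9
150,FALSE,15,-0.9,2.9,-0.4,3.1
155,FALSE,12,-2.6,2.6,-1.9,2.7
161.3,TRUE,12,-6.1,2.6,-6.1,2.6
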