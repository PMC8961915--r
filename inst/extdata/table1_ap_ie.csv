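angle,is_maxflex,n,posterior_flex,posterior_flex_sd,posterior_ext,posterior_ext_sd,external_flex,external_flex_sd,external_ext,external_ext_sd
100,FALSE,11,-5.6,3.2,-4.5,3.0,-0.6,5.0,11.8,6.7
105,FALSE,13,-3.7,3.1,-2.7,3.2,1.0,6.8,13.8,6.5
110,FALSE,14,-1.5,3.1,-0.5,3.5,2.4,7.3,15.2,6.2
115,FALSE,15,1.2,3.7,2.1,4.3,2.8,7.5,16.9,6.4
120,FALSE,15,3.6,3.8,4.3,4.6,4.2,7.7,18.1,6.4
125,FALSE,15,6.2,4.1,6.6,4.7,5.8,7.4,19.0,6.3
130,FALSE,15,8.9,4.2,9.1,4.6,7.7,6.7,19.6,6.3
135,FALSE,15,11.7,4.2,11.9,4.5,10.1,5.8,20.0,6.4
140,FALSE,15,14.8,4.1,14.9,4.4,12.5,4.9,20.1,6.6
145,FALSE,15,18.2,4.1,18.4,4.3,14.9,4.6,20.4,6.7
150,FALSE,15,22.1,4.2,22.2,4.3,16.6,4.9,20.5,6.5
155,FALSE,12,26.2,4.7,26.1,4.6,18.5,5.2,22.3,5.4
161.3,TRUE,12,31.9,5.5,31.9,5.5,19.2,5.0,19.2,5.0
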