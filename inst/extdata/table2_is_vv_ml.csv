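angle,is_maxflex,n,superior_flex,superior_flex_sd,superior_ext,superior_ext_sd,varus_flex,varus_flex_sd,varus_ext,varus_ext_sd,medial_flex,medial_flex_sd,medial_ext,medial_ext_sd
100,FALSE,11,38.8,3.1,38.2,2.8,5.7,3.5,4.6,3.5,2.8,3.5,1.0,3.3
105,FALSE,13,39.2,2.9,38.7,2.7,5.5,3.4,4.5,3.2,2.8,3.2,1.5,2.9
110,FALSE,14,40.1,2.9,39.5,2.6,5.2,3.3,4.0,3.1,2.6,3.0,1.6,2.6
115,FALSE,15,40.9,3.1,39.5,2.7,5.2,3.1,3.7,2.8,2.6,2.9,2.2,2.5
120,FALSE,15,41.0,3.0,40.4,2.6,5.1,3.1,3.6,2.5,2.6,2.9,2.9,2.4
125,FALSE,15,41.0,2.9,40.4,2.5,4.9,3.2,3.3,2.3,2.6,3.0,3.6,2.5
130,FALSE,15,40.8,2.7,40.2,2.4,4.5,3.3,2.9,2.2,2.8,3.1,4.1,2.6
135,FALSE,15,10.4,2.5,39.9,2.3,4.1,3.2,2.5,2.2,3.4,3.5,4.7,2.9
140,FALSE,15,39.8,2.2,39.3,2.1,3.5,3.3,2.1,2.1,4.2,3.9,5.5,3.3
145,FALSE,15,39.0,1.9,38.4,1.9,2.7,3.3,1.4,2.3,5.0,4.2,6.1,3.6
150,FALSE,15,38.0,1.7,37.4,1.9,1.7,3.3,0.6,2.6,5.7,4.3,6.7,3.7
155,FALSE,12,36.2,1.6,35.8,1.9,1.0,3.5,-0.1,3.1,7.4,3.2,7.9,2.9
161.3,TRUE,12,34.1,2.1,34.1,2.1,-0.2,3.6,-0.2,3.6,8.6,3.4,8.6,3.4
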