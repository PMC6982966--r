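id,tested_ic50_nM,tested_pic50,predicted_ic50_nM,predicted_pic50
4d,1090,5.9620,116,6.9346
4i,210,6.6770,48,7.3107
4j,140,6.8540,74,7.1318
4q,3210,5.4930,201,6.6959
5a,2220,5.6530,560,6.2513
5c,2760,5.559,333,6.4781
5f,2930,5.5330,475,6.3235
6a,1780,5.749,210,6.6764
6c,1580,5.801,325,6.4858
6e,4160,5.3810,524,6.2800
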