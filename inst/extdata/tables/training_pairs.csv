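id,tested_ic50_nM,tested_pic50,predicted_ic50_nM,predicted_pic50
4e,1400,5.8540,2745,5.5610
4f,4100,5.3870,2050,5.6888
4g,360,6.4440,304,6.5177
4h,110,6.9580,98,7.0060
4p,1520,5.8180,1490,5.8394
4r,520,6.2840,666,6.1762
4s,1510,5.8210,1285,5.8909
4v,25,7.6020,27,7.5749
4w,110,6.9580,108,6.9667
4x,170,6.7690,220,6.6584
4y,610,6.2150,600,6.2178
5d,2000,5.6980,2490,5.6058
5g,560,6.2520,549,6.2605
5h,480,6.3180,580,6.2371
5j,1270,5.8960,1060,5.9747
5k,1650,5.8380,1230,5.9210
6b,1120,5.950,1050,5.9779
6d,1350,5.8690,1417,5.8485
6f,870,6.0600,590,6.2289
6g,430,6.3660,708,6.1497
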