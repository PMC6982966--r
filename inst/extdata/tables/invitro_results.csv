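zinc_code,inhibition_pct_10uM,ic50_nM,rough_estimate,predicted_ic50_nM,predicted_pic50
01893208,39,12000,TRUE,845,6.0711
37867960,35,14000,TRUE,4650,5.3323
00082235,75,2330,FALSE,1145,5.9413
01236034,45,11000,TRUE,0.08,10.0672
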