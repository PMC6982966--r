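zinc_code,predicted_ic50_nM,predicted_pic50,s_score
01893208,849,6.0711,-7.0598
37867960,4650,5.3323,-7.0005
02700659,292,6.5347,-7.0460
01214105,2930,5.5334,-6.5439
00082235,1145,5.9413,-6.7446
00978111,245500,3.6018,-6.0406
53166374,82,7.0870,-6.4533
02700667,8550,5.0684,-6.6746
01236034,0.08,10.0672,-6.4042
01236036,3900,5.4007,-6.3467
01236042,5700,5.2432,-6.8031
01236043,28500,4.5408,-6.8501
01236046,900000,3.0440,-7.0466
002700665,1180000,2.9347,-6.9187
00449156,71,7.1470,-5.8886
0079314,61,7.2195,-6.8687
04776566,46600,4.3312,-6.2294
00720964,19,7.7102,-6.6344
10034949,21,7.6758,-6.7250
10034950,3500000,2.4537,-6.2979
00065262,11,7.9146,-5.9976
01214623,16000000,1.7974,-6.4351
05776381,8550,5.0608,-6.2530
10034955,108000,3.9677,-6.1499
00721112,450,6.333,-6.6130
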