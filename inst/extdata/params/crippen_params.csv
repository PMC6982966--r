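type,logp,mr
C1,0.1441,2.503
C2,0,2.433
C3,-0.2035,2.753
C4,-0.2051,2.731
C5,-0.2783,5.007
C6,0.1551,3.513
C7,0.0017,3.888
C8,0.08452,2.464
C9,-0.1444,2.412
C10,-0.0516,2.488
C11,0.1193,2.582
C12,-0.0967,2.576
C13,-0.5443,4.041
C14,0,3.257
C15,0.245,3.564
C16,0.198,3.18
C17,0,3.104
C18,0.1581,3.35
C19,0.2955,4.346
C20,0.2713,3.904
C21,0.136,3.509
C22,0.4619,4.067
C23,0.5437,3.853
C24,0.1893,2.673
C25,-0.8186,3.135
C26,0.264,4.305
C27,0.2148,2.693
CS,0.08129,3.243
H1,0.123,1.057
H2,-0.2677,1.395
H3,0.2142,0.9627
H4,0.298,1.805
HS,0.1125,1.112
N1,-1.019,2.262
N2,-0.7096,2.173
N3,-1.027,2.827
N4,-0.5188,3
N5,0.08387,1.757
N6,0.1836,2.428
N7,-0.3187,1.839
N8,-0.4458,2.819
N9,0.01508,1.725
N10,-1.95,0
N11,-0.3239,2.202
N12,-1.119,0
N13,-0.3396,0.2604
N14,0.2887,3.359
NS,-0.4806,2.134
O1,0.1552,1.08
O2,-0.2893,0.8238
O3,-0.0684,1.085
O4,-0.4195,1.182
O5,0.0335,3.367
O6,-0.3339,0.7774
O12,-1.326,0
O7,-1.189,0
O8,0.1788,3.135
O9,-0.1526,0
O10,0.1129,0.2215
O11,0.4833,0.389
OS,-0.1188,0.6865
F,0.4202,1.108
Cl,0.6895,5.853
Br,0.8456,8.927
I,0.8857,14.02
Hal,-2.996,0
P,0.8612,6.92
S1,0.6482,7.591
S2,-0.0024,7.365
S3,0.6237,6.691
Me1,-0.3808,5.754
Me2,-0.0025,0
UNK,0,0
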