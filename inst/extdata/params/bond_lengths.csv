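elem1,elem2,order,length
C,C,1,1.54
C,C,1.5,1.39
C,C,2,1.34
C,C,3,1.20
C,N,1,1.47
C,N,1.5,1.35
C,N,2,1.28
C,N,3,1.15
C,O,1,1.43
C,O,1.5,1.36
C,O,2,1.21
C,S,1,1.82
C,S,1.5,1.71
C,S,2,1.60
C,H,1,1.09
N,H,1,1.01
O,H,1,0.96
S,H,1,1.34
N,N,1,1.45
N,N,1.5,1.35
N,N,2,1.25
N,N,3,1.10
N,O,1,1.40
N,O,1.5,1.30
N,O,2,1.21
O,O,1,1.48
S,S,1,2.05
S,O,1,1.57
S,O,2,1.44
C,F,1,1.35
C,Cl,1,1.77
C,Br,1,1.94
C,I,1,2.14
C,P,1,1.84
P,O,1,1.63
P,O,2,1.48
P,H,1,1.42
C,B,1,1.56
C,Si,1,1.86
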