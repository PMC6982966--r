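family,name,lower,upper
peoe,width,0.05,0.05
qpolar,cutoff,0.20,0.20
slogp,SlogP_VSA7,0.25,0.30
slogp,SlogP_VSA8,0.30,0.40
slogp,SlogP_VSA9,0.40,Inf
smr,SMR_VSA5,0.44,0.485
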