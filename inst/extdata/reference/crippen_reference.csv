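mol_id,smiles,slogp,smr
ethane,CC,1.0262,11.348
ethanol,CCO,-0.0014,12.7598
isopropanol,CC(C)O,0.3871,17.3548
diethyl_ether,CCOCC,1.0428,22.167
thf,C1CCOC1,0.7968,20.053
acetone,CC(=O)C,0.5953,16.355
acetic_acid,CC(=O)O,0.0909,13.3098
methyl_acetate,CC(=O)OC,0.1793,17.69
acetamide,CC(=O)N,-0.5084,14.8684
ethylamine,CCN,-0.035,14.7284
acetonitrile,CC#N,0.5299,11.287
benzene,c1ccccc1,1.6866,26.442
toluene,Cc1ccccc1,1.995,31.179
phenol,Oc1ccccc1,1.3922,28.1068
aniline,Nc1ccccc1,1.2688,30.8544
pyridine,c1ccncc1,1.0816,24.237
furan,c1ccoc1,1.2796,18.708
pyrrole,c1cc[nH]c1,1.0147,20.7927
chloroethane,CCCl,1.2451,16.394
bromoethane,CCBr,1.4012,19.468
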