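mol_id,smiles,atom,symbol,charge,h_charge,n_h
ethane,CC,1,C,-0.068262,0.022754,3
ethane,CC,2,C,-0.068262,0.022754,3
ethanol,CCO,1,C,-0.041838,0.025373,3
ethanol,CCO,2,C,0.040221,0.05607,2
ethanol,CCO,3,O,-0.396664,0.210022,1
isopropanol,CC(C)O,1,C,-0.039228,0.025659,3
isopropanol,CC(C)O,2,C,0.048348,0.059446,1
isopropanol,CC(C)O,3,C,-0.039228,0.025659,3
isopropanol,CC(C)O,4,O,-0.393707,0.210416,1
diethyl_ether,CCOCC,1,C,-0.041565,0.025383,3
diethyl_ether,CCOCC,2,C,0.043708,0.05636,2
diethyl_ether,CCOCC,3,O,-0.382026,,0
diethyl_ether,CCOCC,4,C,0.043708,0.05636,2
diethyl_ether,CCOCC,5,C,-0.041565,0.025383,3
thf,C1CCOC1,1,C,-0.027414,0.029094,2
thf,C1CCOC1,2,C,-0.027414,0.029094,2
thf,C1CCOC1,3,C,0.046638,0.056656,2
thf,C1CCOC1,4,O,-0.381449,,0
thf,C1CCOC1,5,C,0.046638,0.056656,2
acetone,CC(=O)C,1,C,-0.005962,0.031,3
acetone,CC(=O)C,2,C,0.126268,,0
acetone,CC(=O)C,3,O,-0.300344,,0
acetone,CC(=O)C,4,C,-0.005962,0.031,3
acetic_acid,CC(=O)O,1,C,0.033768,0.034848,3
acetic_acid,CC(=O)O,2,C,0.299685,,0
acetic_acid,CC(=O)O,3,O,-0.25282,,0
acetic_acid,CC(=O)O,4,O,-0.481433,0.296257,1
methyl_acetate,CC(=O)OC,1,C,0.033933,0.034854,3
methyl_acetate,CC(=O)OC,2,C,0.301847,,0
methyl_acetate,CC(=O)OC,3,O,-0.252647,,0
methyl_acetate,CC(=O)OC,4,O,-0.469198,,0
methyl_acetate,CC(=O)OC,5,C,0.080575,0.066976,3
acetamide,CC(=O)N,1,C,0.014604,0.033015,3
acetamide,CC(=O)N,2,C,0.21379,,0
acetamide,CC(=O)N,3,O,-0.275698,,0
acetamide,CC(=O)N,4,N,-0.369921,0.159089,2
ethylamine,CCN,1,C,-0.052905,0.024324,3
ethylamine,CCN,2,C,-0.010576,0.042261,2
ethylamine,CCN,3,N,-0.330748,0.118368,2
acetonitrile,CC#N,1,C,0.023601,0.038781,3
acetonitrile,CC#N,2,C,0.058715,,0
acetonitrile,CC#N,3,N,-0.198658,,0
benzene,c1ccccc1,1,C,-0.062269,0.062269,1
benzene,c1ccccc1,2,C,-0.062269,0.062269,1
benzene,c1ccccc1,3,C,-0.062269,0.062269,1
benzene,c1ccccc1,4,C,-0.062269,0.062269,1
benzene,c1ccccc1,5,C,-0.062269,0.062269,1
benzene,c1ccccc1,6,C,-0.062269,0.062269,1
toluene,Cc1ccccc1,1,C,-0.039775,0.027965,3
toluene,Cc1ccccc1,2,C,-0.051133,,0
toluene,Cc1ccccc1,3,C,-0.059326,0.06255,1
toluene,Cc1ccccc1,4,C,-0.062005,0.062278,1
toluene,Cc1ccccc1,5,C,-0.062249,0.062269,1
toluene,Cc1ccccc1,6,C,-0.062005,0.062278,1
toluene,Cc1ccccc1,7,C,-0.059326,0.06255,1
phenol,Oc1ccccc1,1,O,-0.507967,0.293092,1
phenol,Oc1ccccc1,2,C,0.115075,,0
phenol,Oc1ccccc1,3,C,-0.020229,0.066181,1
phenol,Oc1ccccc1,4,C,-0.058594,0.062405,1
phenol,Oc1ccccc1,5,C,-0.062,0.062273,1
phenol,Oc1ccccc1,6,C,-0.058594,0.062405,1
phenol,Oc1ccccc1,7,C,-0.020229,0.066181,1
aniline,Nc1ccccc1,1,N,-0.398729,0.156216,2
aniline,Nc1ccccc1,2,C,0.031348,,0
aniline,Nc1ccccc1,3,C,-0.039174,0.064449,1
aniline,Nc1ccccc1,4,C,-0.060222,0.062345,1
aniline,Nc1ccccc1,5,C,-0.062118,0.062271,1
aniline,Nc1ccccc1,6,C,-0.060222,0.062345,1
aniline,Nc1ccccc1,7,C,-0.039174,0.064449,1
pyridine,c1ccncc1,1,C,-0.059209,0.06238,1
pyridine,c1ccncc1,2,C,-0.04382,0.063897,1
pyridine,c1ccncc1,3,C,0.026729,0.083978,1
pyridine,c1ccncc1,4,N,-0.264737,,0
pyridine,c1ccncc1,5,C,0.026729,0.083978,1
pyridine,c1ccncc1,6,C,-0.04382,0.063897,1
furan,c1ccoc1,1,C,-0.023854,0.065653,1
furan,c1ccoc1,2,C,-0.023854,0.065653,1
furan,c1ccoc1,3,C,0.090202,0.104318,1
furan,c1ccoc1,4,O,-0.472638,,0
furan,c1ccoc1,5,C,0.090202,0.104318,1
pyrrole,c1cc[nH]c1,1,C,-0.044728,0.063865,1
pyrrole,c1cc[nH]c1,2,C,-0.044728,0.063865,1
pyrrole,c1cc[nH]c1,3,C,0.000496,0.08153,1
pyrrole,c1cc[nH]c1,4,N,-0.367637,0.165311,1
pyrrole,c1cc[nH]c1,5,C,0.000496,0.08153,1
chloroethane,CCCl,1,C,-0.051629,0.024244,3
chloroethane,CCCl,2,C,0.019457,0.043229,2
chloroethane,CCCl,3,Cl,-0.127018,,0
bromoethane,CCBr,1,C,-0.055553,0.023882,3
bromoethane,CCBr,2,C,0.000281,0.038367,2
bromoethane,CCBr,3,Br,-0.093108,,0
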