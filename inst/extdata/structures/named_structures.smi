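# SMILES reconstructed from published IUPAC names (name-derived synthetic
# stand-ins: the original structure files are not deposited; regiochemical
# detail follows the systematic names).
CC(C)n1c2CCCC(=O)c2c2C(=O)c3c(C)cccc3c21 4h
CC(C)n1c2CCCC(=O)c2c2C(=O)c3c(Br)cc(Br)cc3c21 4w
CC1=C(C(=O)NCCCn2cc[nH+]c2)C2=C(O1)C(=O)c1ccccc1C2=O 01893208
CC1=C(C(=O)NCc2cccnc2)C2=C(O1)C(=O)c1ccccc1C2=O 37867960
CC1=C(C(=O)NCCC(C)C)C2=C(O1)C(=O)c1ccccc1C2=O 00082235
CC1=C(C(=O)N2CCOCC2)C2=C(O1)C(=O)c1ccccc1C2=O 01236034
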