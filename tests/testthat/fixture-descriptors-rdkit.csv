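name,smiles,Xp4dv,Xp6dv,Xp7dv,ASA
benzene,c1ccccc1,0.38490017945975075,0.03703703703703707,0.0,37.43140311949697
naphthalene,c1ccc2ccccc2c1,1.132905824745182,0.35911675639654217,0.18595281267272945,60.11306765123217
anthraquinone,O=C1c2ccccc2C(=O)c2ccccc21,2.048410258975007,0.8295890275328028,0.49825921354936814,92.53559460091252
benzoquinone,O=C1C=CC(=O)C=C1,0.4396439643289409,0.07313869894042926,0.011340230290662869,46.50196858200238
caffeine,CN1C=NC2=C1C(=O)N(C(=O)N2C)C,1.471179885323762,0.4554775416244512,0.2115409669035594,79.02895701814933
aspirin,CC(=O)Oc1ccccc1C(=O)O,0.8871712192374142,0.22609323194458789,0.08318789949757663,74.75705264447721
thiophene,c1ccsc1,0.680413817439772,0.0,0.0,35.07176638990846
pyridine,c1ccncc1,0.31260202740993526,0.028688765527462367,0.0,36.651051100443475
pyrrole,c1cc[nH]c1,0.27777777777777796,0.0,0.0,30.64056354051127
phenothiazine,c1ccc2c(c1)Nc1ccccc1S2,2.569567133556142,1.2435776782694707,0.7937093402930581,87.15563838100506
hexane,CCCCCC,0.49999999999999983,0.0,0.0,40.563961599812586
diethyl_ether,CCOCC,0.2041241452319315,0.0,0.0,32.94762260052625
methane,C,0.0,0.0,0.0,8.739251027829551
tcaq,N#CC(C#N)=C1c2ccccc2C(=C(C#N)C#N)c2ccccc21,2.9407004589821937,1.360513964735726,0.8554763781046297,137.17549753085336
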