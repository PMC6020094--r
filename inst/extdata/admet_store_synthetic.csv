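entry_id,smiles,cas,iupac_name,class,subclass,value,reference
S0001,CCO,64-17-5,ethanol,basic,physchem,0.5,synthetic demo entry
S0002,CC(=O)Oc1ccccc1C(=O)O,50-78-2,2-acetyloxybenzoic acid,A,HIA,0.92,synthetic demo entry
S0003,CC(=O)Nc1ccc(O)cc1,103-90-2,N-(4-hydroxyphenyl)acetamide,T,DILI,0.31,synthetic demo entry
S0004,Cn1cnc2c1c(=O)n(C)c(=O)n2C,58-08-2,"1,3,7-trimethylpurine-2,6-dione",M,CYP1A2,0.77,synthetic demo entry
S0005,c1ccccc1,71-43-2,benzene,T,Ames,0.12,synthetic demo entry
S0006,CC(C)Cc1ccc(cc1)C(C)C(=O)O,15687-27-1,2-[4-(2-methylpropyl)phenyl]propanoic acid,A,PPB,0.99,synthetic demo entry
S0007,c1ccc2ccccc2c1,91-20-3,naphthalene,basic,physchem,-3.6,synthetic demo entry
S0008,CCN(CC)CC,121-44-8,"N,N-diethylethanamine",basic,physchem,0.7,synthetic demo entry
S0009,Oc1ccccc1,108-95-2,phenol,T,skin,0.44,synthetic demo entry
S0010,ClC(Cl)Cl,67-66-3,trichloromethane,T,LD50,-1.2,synthetic demo entry
S0011,CC(=O)C,67-64-1,propan-2-one,basic,physchem,1.0,synthetic demo entry
S0012,NC(=O)c1ccccc1,55-21-0,benzamide,D,BBB,0.21,synthetic demo entry
S0013,COc1ccccc1,100-66-3,methoxybenzene,basic,physchem,-1.9,synthetic demo entry
S0014,CCCCCC,110-54-3,hexane,basic,physchem,-3.8,synthetic demo entry
S0015,OCC(O)CO,56-81-5,"propane-1,2,3-triol",E,CL,2.1,synthetic demo entry
S0016,Nc1ccccc1,62-53-3,aniline,T,Ames,0.68,synthetic demo entry
S0017,OC(=O)c1ccccc1,65-85-0,benzoic acid,E,T12,0.9,synthetic demo entry
S0018,C1CCNCC1,110-89-4,piperidine,basic,physchem,1.1,synthetic demo entry
S0019,CSc1ccccc1,100-68-5,methylsulfanylbenzene,M,CYP3A4,0.55,synthetic demo entry
S0020,OCCO,107-21-1,"ethane-1,2-diol",E,VD,0.54,synthetic demo entry
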