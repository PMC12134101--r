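backbone	smiles
CE	CC(C)CCCC(C)C1CCC2C3CC=C4CC(OC(C)=O)CCC4(C)C3CCC12C
ST	CC(C)CCCC(C)C1CCC2C3CC=C4CC(O)CCC4(C)C3CCC12C
FA	CC(=O)O
MG	CC(=O)OCC(O)CO
DG	CC(=O)OCC(OC(C)=O)CO
TG	CC(=O)OCC(OC(C)=O)COC(C)=O
PC	CC(=O)OCC(OC(C)=O)COP(=O)([O-])OCC[N+](C)(C)C
PE	CC(=O)OCC(OC(C)=O)COP(=O)(O)OCCN
etherPE	CCOCC(OC(C)=O)COP(=O)(O)OCCN
PS	CC(=O)OCC(OC(C)=O)COP(=O)(O)OCC(N)C(=O)O
PI	CC(=O)OCC(OC(C)=O)COP(=O)(O)OC1C(O)C(O)C(O)C(O)C1O
PG	CC(=O)OCC(OC(C)=O)COP(=O)(O)OCC(O)CO
PA	CC(=O)OCC(OC(C)=O)COP(=O)(O)O
CL	OCC(O)COP(=O)(O)OCC(O)COP(=O)(O)OCC(O)CO
LPC	CC(=O)OCC(O)COP(=O)([O-])OCC[N+](C)(C)C
LPE	CC(=O)OCC(O)COP(=O)(O)OCCN
LPA	CC(=O)OCC(O)COP(=O)(O)O
LPI	CC(=O)OCC(O)COP(=O)(O)OC1C(O)C(O)C(O)C(O)C1O
LPS	CC(=O)OCC(O)COP(=O)(O)OCC(N)C(=O)O
SM	CC=CC(O)C(COP(=O)([O-])OCC[N+](C)(C)C)NC(C)=O
Cer	CC=CC(O)C(CO)NC(C)=O
HexCer	CC=CC(O)C(COC1OC(CO)C(O)C(O)C1O)NC(C)=O
Hex2Cer	CC=CC(O)C(COC1OC(CO)C(O)C(O)C1OC2OC(CO)C(O)C(O)C2O)NC(C)=O
GM3	CC=CC(O)C(COC1OC(CO)C(O)C(O)C1OC2OC(CO)C(O)C(C2O)OC3OC(C(=O)O)CC(NC(C)=O)C3O)NC(C)=O
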