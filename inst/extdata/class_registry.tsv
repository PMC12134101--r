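subclass	category	scaffold_formula	n_chain_slots	linkage	backbone
CE	NL	C27H46O	1	ester	CE
ST	ST	C27H46O	0	none	ST
FA	NL	-	1	free	FA
MG	NL	C3H8O3	1	ester	MG
DG	NL	C3H8O3	2	ester	DG
TG	NL	C3H8O3	3	ester	TG
PC	GPL	C8H20NO6P	2	ester	PC
PE	GPL	C5H14NO6P	2	ester	PE
etherPE	GPL	C5H14NO6P	2	ether	etherPE
PS	GPL	C6H14NO8P	2	ester	PS
PI	GPL	C9H19O11P	2	ester	PI
PG	GPL	C6H15O8P	2	ester	PG
PA	GPL	C3H9O6P	2	ester	PA
CL	GPL	C9H22O13P2	4	ester	CL
LPC	lysoGPL	C8H20NO6P	1	ester	LPC
LPE	lysoGPL	C5H14NO6P	1	ester	LPE
LPA	lysoGPL	C3H9O6P	1	ester	LPA
LPI	lysoGPL	C9H19O11P	1	ester	LPI
LPS	lysoGPL	C6H14NO8P	1	ester	LPS
SM	SP	C5H12NO3P	2	sphingo	SM
Cer	SP	-	2	sphingo	Cer
dhCer	SP	-	2	sphingo	Cer
deoxyCer	SP	-	2	sphingo	Cer
phytoCer	SP	-	2	sphingo	Cer
sphdCer	SP	-	2	sphingo	Cer
HexCer	SP	C6H10O5	2	sphingo	HexCer
Hex2Cer	SP	C12H20O10	2	sphingo	Hex2Cer
GM3	SP	C23H37NO18	2	sphingo	GM3
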