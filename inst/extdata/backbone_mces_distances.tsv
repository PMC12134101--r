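backbone	CE	ST	FA	MG	DG	TG	PC	PE	etherPE	PS	PI	PG	PA	CL	LPC	LPE	LPA	LPI	LPS	SM	Cer	HexCer	Hex2Cer	GM3
CE	0	3	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15
ST	3	0	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15
FA	15	15	0	5	8	11	15	15	14	15	15	15	12	15	15	12	9	15	15	15	10	15	15	15
MG	15	15	5	0	3	6	13	10	11	13	15	12	7	15	10	7	4	15	10	15	7	15	15	15
DG	15	15	8	3	0	3	10	7	8	10	15	9	4	15	11	8	7	15	9	15	8	15	15	15
TG	15	15	11	6	3	0	11	8	9	9	15	10	7	15	14	11	10	15	12	15	11	15	15	15
PC	15	15	15	13	10	11	0	3	4	6	14	7	6	15	3	6	9	15	7	8	15	15	15	15
PE	15	15	15	10	7	8	3	0	1	3	11	4	3	15	6	3	6	12	4	11	13	15	15	15
etherPE	15	15	14	11	8	9	4	1	0	4	12	5	4	15	7	4	7	13	5	10	12	15	15	15
PS	15	15	15	13	10	9	6	3	4	0	10	3	6	15	9	6	9	11	3	14	15	15	15	15
PI	15	15	15	15	15	15	14	11	12	10	0	7	12	12	15	14	15	3	13	15	15	15	15	15
PG	15	15	15	12	9	10	7	4	5	3	7	0	5	13	10	7	8	8	6	15	15	15	15	15
PA	15	15	12	7	4	7	6	3	4	6	12	5	0	15	7	4	3	13	5	14	12	15	15	15
CL	15	15	15	15	15	15	15	15	15	15	12	13	15	0	15	14	15	9	13	15	15	15	15	15
LPC	15	15	15	10	11	14	3	6	7	9	15	10	7	15	0	3	6	14	6	7	15	15	15	15
LPE	15	15	12	7	8	11	6	3	4	6	14	7	4	14	3	0	3	11	3	10	12	15	15	15
LPA	15	15	9	4	7	10	9	6	7	9	15	8	3	15	6	3	0	12	6	13	11	15	15	15
LPI	15	15	15	15	15	15	15	12	13	11	3	8	13	9	14	11	12	0	10	15	15	15	15	15
LPS	15	15	15	10	9	12	7	4	5	3	13	6	5	13	6	3	6	10	0	13	13	15	15	15
SM	15	15	15	15	15	15	8	11	10	14	15	15	14	15	7	10	13	15	13	0	10	15	15	15
Cer	15	15	10	7	8	11	15	13	12	15	15	15	12	15	15	12	11	15	13	10	0	12	15	15
HexCer	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	12	0	12	15
Hex2Cer	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	12	0	15
GM3	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	15	0
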