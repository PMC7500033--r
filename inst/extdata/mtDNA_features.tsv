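name	start	end	category
control_region	16024	575	control_region
oriL	5721	5798	origin
7S_3prime	16024	16106	origin
minor_arc	16071	5779	arc
major_arc	5781	16069	arc
PL_promoter	392	445	promoter
PH_promoter	545	567	promoter
RNR1	648	1601	rRNA
RNR2	1671	3229	rRNA
TERM_L1	3230	3256	terminator
TF	577	647	tRNA
TV	1602	1670	tRNA
TL1	3257	3304	tRNA
ND1	3307	4262	gene
ND2	4470	5511	gene
CO1	5904	7445	gene
CO2	7586	8269	gene
TK	8295	8364	tRNA
ATP8	8366	8572	gene
ATP6	8527	9207	gene
CO3	9208	9990	gene
ND3	10059	10404	gene
ND4L	10470	10766	gene
ND4	10767	12137	gene
TH	12138	12206	tRNA
TS2	12207	12265	tRNA
TL2	12266	12336	tRNA
ND5	12337	14148	gene
ND6	14149	14673	gene
TE	14674	14742	tRNA
CYB	14747	15887	gene
TT	15888	15953	tRNA
TP	15956	16023	tRNA
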