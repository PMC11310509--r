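tf	predicted_class	status	literature_classes
PRDM13	AC	Matched	AC
HES6	AC	Unmatched	Rod
POU2F2	AC	Unmatched	Cone
ID2	AC	Unknown
ST18	AC	Unknown
NFIB	BC	Matched	BC
OTX2	BC	Matched	BC
PRDM8	BC	Matched	BC
VSX1	BC	Matched	BC
VSX2	BC	Matched	BC
NEUROD1	BC	Unmatched	Cone,Rod
RORA	BC	Unknown
SKOR2	BC	Unknown
FOXN4	Cone	Matched	Cone
PRDM1	Cone	Matched	Cone
THRB	Cone	Matched	Cone
ID3	Cone	Unknown
CUX2	Cone	Unknown
FOS	Cone	Unknown
FOSB	Cone	Unknown
MEIS2	Cone	Unknown
NPAS3	Cone	Unknown
NR4A1	Cone	Unknown
NR4A3	Cone	Unknown
RUNX1	Cone	Unknown
RXRG	Cone	Unknown
ONECUT1	HC	Matched	HC
ONECUT2	HC	Matched	HC
PROX1	HC	Matched	HC
TFAP2A	HC	Matched	HC
TFAP2B	HC	Matched	HC
EBF1	HC	Unknown
ESRRB	HC	Unknown
ESRRG	HC	Unknown
HIVEP3	HC	Unknown
MYT1L	HC	Unknown
ONECUT3	HC	Unknown
PRDM6	HC	Unknown
TSHZ2	HC	Unknown
TSHZ3	HC	Unknown
ZFHX3	HC	Unknown
ZFPM2	HC	Unknown
ATOH7	RGC	Matched	RGC
ISL1	RGC	Matched	RGC
PBX4	RGC	Matched	RGC
POU4F2	RGC	Matched	RGC
EGR1	RGC	Unmatched	AC,HC
ZIC1	RGC	Unmatched	Rod
E2F7	RGC	Unknown
EBF2	RGC	Unknown
EBF3	RGC	Unknown
FOXM1	RGC	Unknown
HES5	RGC	Unknown
LEF1	RGC	Unknown
MECOM	RGC	Unknown
MXD3	RGC	Unknown
MYBL1	RGC	Unknown
PAX5	RGC	Unknown
PBX3	RGC	Unknown
POU6F2	RGC	Unknown
SOX5	RGC	Unknown
SP8	RGC	Unknown
TFAP2D	RGC	Unknown
ZNF367	RGC	Unknown
ZNF730	RGC	Unknown
CRX	Rod	Matched	Rod
HMGA2	Rod	Matched	Rod
NR2E3	Rod	Matched	Rod
NRL	Rod	Matched	Rod
HES1	Rod	Unmatched	Cone
MEF2C	Rod	Unmatched	Cone
NFIA	Rod	Unmatched	BC
NFIX	Rod	Unmatched	BC
RARB	Rod	Unmatched	RGC
ARID5B	Rod	Unknown
ASCL1	Rod	Unknown
BACH2	Rod	Unknown
BHLHE41	Rod	Unknown
CREB5	Rod	Unknown
EPAS1	Rod	Unknown
ETV1	Rod	Unknown
ETV5	Rod	Unknown
GLIS3	Rod	Unknown
HIF3A	Rod	Unknown
JAZF1	Rod	Unknown
MITF	Rod	Unknown
NR3C2	Rod	Unknown
PAX2	Rod	Unknown
PAX8	Rod	Unknown
PPARA	Rod	Unknown
RAX2	Rod	Unknown
RREB1	Rod	Unknown
SOX6	Rod	Unknown
TCF7L1	Rod	Unknown
ZBTB7C	Rod	Unknown
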