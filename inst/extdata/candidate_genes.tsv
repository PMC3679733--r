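gene	chr	start	end	pathway
UBE2A	4	16506437	16512992	UMP
MARCH7	7	36187561	36207776	UMP
HERC4	6	10024961	10054292	UMP
ZBTB1	5	52791938	52805593	UMP
MID1	1	124042084	124134384	UMP
RNF144A	3	94598486	94657682	UMP
NRAS	26	3847830	3854232	ER
ITCH	20	1769346	1829955	UMP
TGFA	22	3012283	3020403	ER
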