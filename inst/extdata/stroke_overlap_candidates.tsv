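GENE	CHR	PANEL	P_TWAS	P_MRNA
CISD1	10	METSIM	0.00357	0.0055
RHOU	1	YFS	0.00375	0.0276
TM6SF1	15	METSIM	0.0136	0.0452
TM6SF1	15	YFS	0.00586	0.0452
TP53RK	20	YFS	0.00803	0.0205
CLDN5	22	YFS	0.00804	0.0008
NFKBIA	14	NTR	0.00957	0.0114
MRVI1	11	METSIM	0.00997	0.0359
ZNF667-AS1	19	METSIM	0.01025	0.0019
WDSUB1	2	NTR	0.01414	0.0153
WSB1	17	METSIM	0.04353	0.0348
WSB1	17	YFS	0.01501	0.0348
TPM1	15	NTR	0.01590	0.0302
GOLGA8A	15	YFS	0.01704	0.0062
TIPARP	3	METSIM	0.02357	0.0095
VRK2	2	YFS	0.02953	0.0211
TOR1AIP1	1	NTR	0.0339	0.0051
BARD1	2	METSIM	0.03580	0.0019
BARD1	2	YFS	0.04980	0.0019
BAG5	14	NTR	0.03791	0.0410
VASH1	14	METSIM	0.04918	0.0239
VASH1	14	YFS	0.03802	0.0239
PDIA6	2	YFS	0.04136	0.0031
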