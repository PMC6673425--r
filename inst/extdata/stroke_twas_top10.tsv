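GENE	CHR	ZSCORE	P_TWAS	P_PERM	PANEL
SLC25A44	1	6.2053	5.46E-10	0.00671	METSIM
LRCH1	13	-4.8058	1.54E-06	0.01153	METSIM
FLJ44606	5	4.3540	1.58E-05	0.01150	NTR
PLEKHA1	10	-4.3171	2.39E-05	0.00499	METSIM
ZNF318	6	4.2252	7.04E-05	0.01974	NTR
CD40	20	3.9748	7.67E-05	0.00376	METSIM
FES	15	-3.9545	8.06E-05	0.00515	METSIM
RERE	1	-3.9425	9.77E-05	0.00566	NTR
SLC25A29	14	3.8962	1.15E-04	0.00100	METSIM
LARS	5	3.8558	1.24E-04	0.02459	METSIM
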