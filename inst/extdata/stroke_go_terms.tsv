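CATEGORY	ID	NAME	P
GOTERM_BP_DIRECT	GO:0008360	Regulation of cell shape	0.0059
GOTERM_BP_DIRECT	GO:0060325	Face morphogenesis	0.0247
GOTERM_BP_DIRECT	GO:0032781	Positive regulation of ATPase activity	0.0256
GOTERM_MF_DIRECT	GO:0004842	Ubiquitin-protein transferase activity	0.0336
GOTERM_BP_DIRECT	GO:0016567	Protein ubiquitination	0.0350
GOTERM_MF_DIRECT	GO:0008092	Cytoskeletal protein binding	0.0418
GOTERM_BP_DIRECT	GO:0071407	Cellular response to organic cyclic compound	0.0481
GOTERM_BP_DIRECT	GO:0045732	Positive regulation of protein catabolic process	0.0489
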