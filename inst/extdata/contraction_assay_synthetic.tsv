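condition	positive_colonies	plated_cells	plating_efficiency
DMSO	12	4500000	0.5
SAHA	38	4500000	0.5
MS-275	29	4500000	0.5
splitomicin	21	4500000	0.5
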