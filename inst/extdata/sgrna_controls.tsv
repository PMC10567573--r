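id	sequence	label	group
sg-AAVS1	GGGGCCACTAGGGACAGGAT	AAVS1	safe_harbor_control
sg1-FEM1B	GTGACATAGCCAAGCAGATAG	FEM1B	cul2_adaptor
sg2-FEM1B	GATGTACCTACCCGTCGAAG	FEM1B	cul2_adaptor
sg-APPBP2	GATGTAGTTGTCCACGACAG	APPBP2	cul2_adaptor
sg-GAN	GGTGCAGAAGAACATCCTGG	GAN	cul3_adaptor
sg-FBXO38	GTTGTAGATCTCTGTGCAGGG	FBXO38	cul1_adaptor
sg-KLHL15	GTCTGAAGTAATCACTCTGGG	KLHL15	cul3_adaptor
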