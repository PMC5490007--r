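chr5	1253286	1295162	TERT
chr5	38938022	39074510	RICTOR
chr12	4382901	4414522	CCND2
chr12	58141509	58149796	CDK4
chr12	69201955	69239214	MDM2
chr12	102789644	102874378	IGF1
chr17	7571719	7590868	TP53
chr17	17109722	17139826	COPS3
chr17	29421944	29704695	NF1
chr15	99192199	99507759	IGF1R
chr6	160390130	160534539	IGF2R
chr2	217536827	217560272	IGFBP5
chr3	178866310	178952497	PIK3CA
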