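species	gene_id	exon_index	cds_start	cds_end
Trichechus_manatus_latirostris	GBA3	1	1	297
Trichechus_manatus_latirostris	GBA3	5	1171	1407
Desmodus_rotundus	GBA3	1	1	120
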