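species	gene_id	kind	exon_index	cds_nt_pos	codon_index	indel_len	frameshift	splice_site	observed_site	stop_context	allele	cluster_id	validation	n_supporting_projects
Orcinus_orca	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAA	CET1	validated_fixed	3
Tursiops_truncatus	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAA	CET1	validated_fixed	3
Delphinapterus_leucas	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAA	CET1	validated_fixed	2
Lipotes_vexillifer	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAA	CET1	validated_fixed	2
Physeter_catodon	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAA	CET1	validated_fixed	2
Balaenoptera_acutorostrata	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAA	CET1	validated_fixed	2
Balaena_mysticetus	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAA	CET1	validated_fixed	2
Orcinus_orca	GBA3	premature_stop	3	790	264	0	FALSE	NA	NA	YTTRX	TGA	CET2	validated_fixed	3
Tursiops_truncatus	GBA3	premature_stop	3	790	264	0	FALSE	NA	NA	YTTRX	TGA	CET2	validated_fixed	3
Delphinapterus_leucas	GBA3	premature_stop	3	790	264	0	FALSE	NA	NA	YTTRX	TGA	CET2	validated_fixed	2
Lipotes_vexillifer	GBA3	premature_stop	3	790	264	0	FALSE	NA	NA	YTTRX	TGA	CET2	validated_fixed	2
Physeter_catodon	GBA3	premature_stop	3	790	264	0	FALSE	NA	NA	YTTRX	TGA	CET2	validated_fixed	2
Balaenoptera_acutorostrata	GBA3	premature_stop	3	790	264	0	FALSE	NA	NA	YTTRX	TGA	CET2	validated_fixed	2
Balaena_mysticetus	GBA3	premature_stop	3	790	264	0	FALSE	NA	NA	YTTRX	TGA	CET2	validated_fixed	2
Orcinus_orca	GBA3	deletion	4	1000	334	5	TRUE	NA	NA	NA	ACTGG	ORC1	validated_fixed	2
Balaena_mysticetus	GBA3	insertion	5	1250	417	2	TRUE	NA	NA	NA	TT	BMY1	validated_fixed	2
Phoca_vitulina	GBA3	deletion	3	640	214	13	TRUE	NA	NA	NA	ACTGGACTTCAGT	PHO1	validated_fixed	3
Leptonychotes_weddellii	GBA3	deletion	3	640	214	13	TRUE	NA	NA	NA	ACTGGACTTCAGT	PHO1	validated_fixed	2
Callorhinus_ursinus	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAG	OTA1	validated_fixed	2
Zalophus_californianus	GBA3	premature_stop	3	730	244	0	FALSE	NA	NA	DSLFX	TAG	OTA1	validated_fixed	2
Odobenus_rosmarus_divergens	GBA3	insertion	3	610	204	1	TRUE	NA	NA	NA	A	WAL1	validated_fixed	2
Odobenus_rosmarus_divergens	GBA3	deletion	3	700	234	2	TRUE	NA	NA	NA	CT	WAL2	validated_fixed	2
Odobenus_rosmarus_divergens	GBA3	deletion	3	850	284	1	TRUE	NA	NA	NA	G	WAL3	validated_fixed	2
Vulpes_vulpes	GBA3	deletion	3	615	205	1	TRUE	NA	NA	NA	G	FOX1	validated_polymorphic	2
Lycaon_pictus	GBA3	premature_stop	3	688	230	0	FALSE	NA	NA	KLSEX	TGA	LYC1	validated_polymorphic	2
Mus_musculus	GBA3	premature_stop	3	628	210	0	FALSE	NA	NA	GWNSX	TAA	ROD1	validated_fixed	3
Heterocephalus_glaber	GBA3	premature_stop	3	628	210	0	FALSE	NA	NA	GWNSX	TAA	ROD1	validated_fixed	2
Fukomys_damarensis	GBA3	premature_stop	3	628	210	0	FALSE	NA	NA	GWNSX	TAA	ROD1	validated_fixed	2
Mus_musculus	GBA3	premature_stop	3	856	286	0	FALSE	NA	NA	SPLQX	TGA	ROD2	validated_fixed	3
Heterocephalus_glaber	GBA3	premature_stop	3	856	286	0	FALSE	NA	NA	SPLQX	TGA	ROD2	validated_fixed	2
Fukomys_damarensis	GBA3	premature_stop	3	856	286	0	FALSE	NA	NA	SPLQX	TGA	ROD2	validated_fixed	2
Mus_musculus	GBA3	insertion	4	1005	335	4	TRUE	NA	NA	NA	ACTG	MUS1	validated_fixed	2
Desmodus_rotundus	GBA3	premature_stop	2	448	150	0	FALSE	NA	NA	AVRLX	TAA	VAM1	validated_fixed	2
Desmodus_rotundus	GBA3	deletion	3	820	274	1	TRUE	NA	NA	NA	T	VAM2	validated_fixed	2
Pteropus_vampyrus	GBA3	premature_stop	5	1318	440	0	FALSE	NA	NA	NTLEX	TAA	PTE1	validated_fixed	2
Pteropus_alecto	GBA3	premature_stop	5	1318	440	0	FALSE	NA	NA	NTLEX	TAA	PTE1	validated_fixed	2
Pteropus_alecto	GBA3	premature_stop	3	748	250	0	FALSE	NA	NA	SDGKX	TAA	PAL1	validated_polymorphic	2
Pteropus_vampyrus	GBA3	deletion	3	760	254	10	TRUE	NA	NA	NA	ACTGGACTGG	PVA1	validated_fixed	2
Loxodonta_africana	GBA3	premature_stop	3	598	200	0	FALSE	NA	NA	RPDLX	TAA	ELE1	validated_fixed	2
Loxodonta_africana	GBA3	premature_stop	3	832	278	0	FALSE	NA	NA	TPGSX	TGA	ELE2	validated_fixed	2
Loxodonta_africana	GBA3	premature_stop	3	904	302	0	FALSE	NA	NA	LYKNX	TAA	ELE3	validated_fixed	2
Loxodonta_africana	GBA3	splice_loss	4	913	305	0	FALSE	acceptor	AA	NA	AA	ELE4	validated_fixed	2
Loxodonta_africana	GBA3	premature_stop	4	958	320	0	FALSE	NA	NA	VDEKX	TAA	ELE5	validated_fixed	2
Trichechus_manatus_latirostris	GBA3	premature_stop	3	658	220	0	FALSE	NA	NA	EGFRX	TAA	MAN1	validated_fixed	2
Trichechus_manatus_latirostris	GBA3	premature_stop	3	808	270	0	FALSE	NA	NA	IQPDX	TGA	MAN2	validated_fixed	2
Homo_sapiens	GBA3	premature_stop	5	1366	456	0	FALSE	NA	NA	AELSX	TAA	HUM1	validated_polymorphic	2
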