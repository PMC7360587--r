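variant_id	gene_id	protein_change	consequence	cdna_pos	af_african	af_american	af_east_asian	af_european	af_south_asian	hma	polyphen	sift
rs358231	GBA3	p.Y456X	stop_gained	1368	0.029	0.108	0.2	0.153	0.076	0.018	NA	NA
rs17612341	GBA3	p.R213P	missense	637	0.001	0.007	0.029	0.011	0.001	NA	0.9	0.1
rs182102815	GBA3	p.G182S	missense	544	0.004	0.003	NA	NA	NA	NA	0.9	0.1
rs187070546	GBA3	p.D106N	missense	316	0.001	0.006	0.039	0.001	NA	NA	0.9	0.1
rs533876334	GBA3	p.A15P	missense	43	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs544339352	GBA3	p.C53S	missense	157	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs187359066	GBA3	p.R82C	missense	244	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs529839966	GBA3	p.T88R	missense	263	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs571805473	GBA3	p.P265S	missense	793	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs538886341	GBA3	p.Y281C	missense	842	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs200660617	GBA3	p.V306A	missense	917	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs371662599	GBA3	p.Y347X	stop_gained	1041	0.001	NA	NA	NA	NA	NA	NA	NA
rs200623163	GBA3	p.R389C	missense	1165	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs560225618	GBA3	p.K402E	missense	1204	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs186578587	GBA3	p.L419V	missense	1255	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs371075149	GBA3	p.N422K	missense	1266	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs191769903	GBA3	p.F433L	missense	1297	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs370728701	GBA3	p.V438A	missense	1313	0.001	NA	NA	NA	NA	NA	0.9	0.1
rs421016	GBA	p.L483P	missense	1448	0.002	0.001	0.012	0.002	NA	NA	0.9	0.1
rs76763715	GBA	p.N409S	missense	1226	0.001	NA	NA	0.002	NA	NA	0.9	0.1
rs149171124	GBA	p.E427X	stop_gained	1279	0.001	NA	NA	NA	NA	NA	NA	NA
rs146519305	GBA	p.R534C	missense	1600	0.01	NA	NA	NA	NA	NA	0.9	0.1
rs369068553	GBA	p.V499M	missense	1495	0.001	NA	NA	NA	NA	NA	0.9	0.1
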