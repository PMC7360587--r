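((Loxodonta_africana:0.08,Trichechus_manatus_latirostris:0.09):0.04,(((Homo_sapiens:0.03,Pan_troglodytes:0.03):0.06,(Ictidomys_tridecemlineatus:0.09,(Mus_musculus:0.12,(Heterocephalus_glaber:0.07,Fukomys_damarensis:0.07):0.04):0.03):0.05):0.02,(((Pteropus_vampyrus:0.02,Pteropus_alecto:0.02):0.05,(Desmodus_rotundus:0.08,Myotis_lucifugus:0.08):0.03):0.02,(((Bos_taurus:0.06,Ovis_aries:0.06):0.04,((Balaenoptera_acutorostrata:0.02,Balaena_mysticetus:0.02):0.02,(Physeter_catodon:0.03,(Lipotes_vexillifer:0.025,(Delphinapterus_leucas:0.02,(Orcinus_orca:0.015,Tursiops_truncatus:0.015):0.005):0.005):0.005):0.01):0.05):0.02,((Felis_catus:0.04,Panthera_tigris:0.04):0.05,((Vulpes_vulpes:0.03,(Lycaon_pictus:0.02,Canis_lupus_familiaris:0.02):0.01):0.04,((Odobenus_rosmarus_divergens:0.03,(Callorhinus_ursinus:0.02,Zalophus_californianus:0.02):0.01):0.02,(Phoca_vitulina:0.02,Leptonychotes_weddellii:0.02):0.03):0.03):0.03):0.02):0.02):0.01):0.01);
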