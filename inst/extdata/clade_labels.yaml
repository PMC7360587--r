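# Clade and stem-branch labels for the packaged mammal tree.
# Clade labels cover the edges inside the clade; branch labels mark the
# single stem edge above the MRCA of the listed tips.
clades:
  A1:
    - Odobenus_rosmarus_divergens
    - Callorhinus_ursinus
    - Zalophus_californianus
    - Phoca_vitulina
    - Leptonychotes_weddellii
  A2:
    - Vulpes_vulpes
    - Lycaon_pictus
    - Canis_lupus_familiaris
  A3:
    - Felis_catus
    - Panthera_tigris
  B1:
    - Balaenoptera_acutorostrata
    - Balaena_mysticetus
    - Physeter_catodon
    - Lipotes_vexillifer
    - Delphinapterus_leucas
    - Orcinus_orca
    - Tursiops_truncatus
  B2:
    - Bos_taurus
    - Ovis_aries
  C1:
    - Pteropus_vampyrus
    - Pteropus_alecto
    - Desmodus_rotundus
    - Myotis_lucifugus
  D1:
    - Ictidomys_tridecemlineatus
    - Mus_musculus
    - Heterocephalus_glaber
    - Fukomys_damarensis
branches:
  BranchA1:
    - Odobenus_rosmarus_divergens
    - Callorhinus_ursinus
    - Zalophus_californianus
    - Phoca_vitulina
    - Leptonychotes_weddellii
  BranchB1:
    - Balaenoptera_acutorostrata
    - Balaena_mysticetus
    - Physeter_catodon
    - Lipotes_vexillifer
    - Delphinapterus_leucas
    - Orcinus_orca
    - Tursiops_truncatus
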