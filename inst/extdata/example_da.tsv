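taxon	log2FC
Faecalibacterium_prausnitzii	-2.10
Roseburia_hominis	-1.80
Roseburia_intestinalis	-1.60
Eubacterium_rectale	-2.30
Anaerostipes_hadrus	-1.20
Coprococcus_eutactus	-1.40
Butyrivibrio_fibrisolvens	-0.90
Ruminococcus_bromii	-0.70
[Ruminococcus]_torques	-0.50
Prevotella_copri	0.30
Bacteroides_fragilis	0.20
Bacteroides_uniformis	-0.10
Akkermansia_muciniphila	0.40
Bifidobacterium_longum	0.10
Bifidobacterium_adolescentis	-0.20
Blautia_obeum	0.05
Dialister_invisus	-0.30
Alistipes_putredinis	0.15
Escherichia_coli	1.20
Klebsiella_pneumoniae	0.90
Enterococcus_faecalis	0.60
Ruminococcus_gnavus	0.80
Streptococcus_salivarius	0.25
Veillonella_parvula	0.35
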