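set	accession	n_case	n_control	platform
discovery	GSE84846	99	0	Agilent-014850 4x44K G4112F
discovery	GSE30784	167	62	Affymetrix HG-U133_Plus_2
discovery	GSE37991	40	40	Illumina HumanRef-8 v3.0
discovery	GSE85446	66	0	Agilent-014850 4x44K G4112F
evaluation	GSE25099	57	22	Affymetrix HuEx-1_0-st
validation	GSE89923	57	33	Affymetrix HG-U133_Plus_2
validation	GSE31056	23	73	Affymetrix HG-U133_Plus_2
validation	GSE85195	16	34	Agilent-014850 4x44K G4112F
validation	GSE23558	27	5	Agilent-014850 4x44K G4112F
prognosis	TCGA-HNSC	546	0	RNA-seq
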