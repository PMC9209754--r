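name	donor_species	linked_group	known_additive_effect
qSER1a-gla	glaberrima		16.90
qSER1b-gla	glaberrima		16.21
qSER1b-glu	glumaepatula		27.30
qSER2a-sat	sativa	seg-A35	17.50
qSER2b-sat	sativa	seg-A35	17.50
qSER3a-sat	sativa	seg-A88	14.04
qSER3b-sat	sativa	seg-A88	17.17
qSER3b-glu	glumaepatula		20.20
qSER5-glu	glumaepatula		25.50
qSER8b-gla	glaberrima		20.52
qSER12-gla	glaberrima		14.56
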