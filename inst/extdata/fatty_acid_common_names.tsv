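common_name	class	carbons	double_bonds
lauric acid	FA	12	0
myristic acid	FA	14	0
palmitic acid	FA	16	0
palmitoleic acid	FA	16	1
stearic acid	FA	18	0
oleic acid	FA	18	1
linoleic acid	FA	18	2
linolenic acid	FA	18	3
arachidic acid	FA	20	0
arachidonic acid	FA	20	4
eicosapentaenoic acid	FA	20	5
behenic acid	FA	22	0
erucic acid	FA	22	1
docosahexaenoic acid	FA	22	6
lignoceric acid	FA	24	0
nervonic acid	FA	24	1
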