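family_id	individual_id	father_id	mother_id	sex
fam1	f	0	0	1
fam1	m	0	0	2
fam1	c1	f	m	1
fam1	c2	f	m	2
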