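family_id	individual_id	father_id	mother_id	sex
1	s1	0	0	1
2	s2	0	0	2
3	s3	0	0	1
4	s4	0	0	2
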