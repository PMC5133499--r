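individual_id	1:100
s1	0
s2	1
s3	0
s4	1
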