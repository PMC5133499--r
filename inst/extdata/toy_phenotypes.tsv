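individual_id	y
s1	-1
s2	1
s3	-1
s4	1
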