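target_id	constraint	rank	source_id
B	prey	1	AM1
B	prey	2	AM2
B	prey	3	H
B	prey	4	C
B	beetle	1	M
B	beetle	2	S
M	prey	1	AM1
M	prey	2	H
M	prey	3	AM2
M	prey	4	C
M	beetle	1	S
M	beetle	2	B
S	prey	1	AM1
S	prey	2	H
S	prey	3	AM2
S	prey	4	C
S	beetle	1	M
S	beetle	2	B
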