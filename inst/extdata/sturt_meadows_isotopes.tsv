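taxon_id	role	proxy	mean	sd
B	both	d13C	-23	0.19
B	both	d15N	14.66	0.27
B	both	D14C	32.90	2.30
M	both	d13C	-23.37	0.19
M	both	d15N	15.43	0.53
M	both	D14C	37	2.20
S	both	d13C	-23.60	0.30
S	both	d15N	14.40	0.30
S	both	D14C	22.90	3.10
AM1	source	d13C	-24.14	0.30
AM1	source	d15N	10.71	0.30
AM1	source	D14C	19.90	4.80
AM2	source	d13C	-24.55	0.30
AM2	source	d15N	9.99	0.30
AM2	source	D14C	-3.70	3.60
C	source	d13C	-20.45	0.30
C	source	d15N	13.90	0.30
C	source	D14C	-5.60	5.60
H	source	d13C	-20.60	0.30
H	source	d15N	11.90	0.80
H	source	D14C	-5.60	5.60
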