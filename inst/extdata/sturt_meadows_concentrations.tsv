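taxon_id	pct_C	pct_N
B	60.07	7.20
M	56.65	7.09
S	39.80	5.30
AM1	57.70	2.80
AM2	58.30	2.80
C	0.11	13.90
H	0.10	11.90
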