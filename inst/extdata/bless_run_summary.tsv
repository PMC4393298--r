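sample	protocol	template_cycle_count	pct_lowdiv	pct_control	density_pct	n_reads	pct_q30	pct_barcoded_norm	n_barcoded_mapped
A4	standard	4	100	0	100	81690716	39	1.1	386703
C3	standard	4	100	0	100	93541636	36	1.8	1095261
L5_1	standard	4	50	50	67	44752944	29	1.0	107514
L5_2	standard	4	50	50	67	44752944	63	5.6	704185
L6_1	standard	4	50	50	67	56647313	32	3.0	573393
L6_2	standard	4	50	50	67	56647313	61	9.6	1598766
LT20_1	long_template	20	100	0	60	5094823	86	77.0	2766509
LT20_2	long_template	20	100	0	100	7827274	84	77.0	4100771
LT20_4	long_template	20	10	90	75	6545127	94	80.0	428208
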