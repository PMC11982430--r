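group	stat	ratio_pos_neg	mean_pos_g	mean_neg_g	max_pos_g	min_neg_g	pct_pos_gt2	pct_neg_lt2	pct_abs_gt2	total_per_min	pos_per_min	neg_per_min
CONTROL	median	0.7	1.3	-1.2	2.5	-2.3	0.6	0.1	0.8	127.4	43.6	91.5
CONTROL	iqr	0.8	0.1	0.1	1.0	1.1	0.8	0.8	0.8	179.4	67.4	94.0
LAME	median	0.4	1.3	-1.3	2.7	-2.2	1.6	0.3	3.5	102.2	37.3	66.8
LAME	iqr	0.6	0.5	0.2	1.4	1.1	4.1	2.7	5.8	115.7	54.3	66.2
NONTGMHS	median	0.2	1.4	-1.3	3.9	-3.6	1.7	3.6	6.8	77.8	20.3	60.7
NONTGMHS	iqr	0.2	0.4	0.3	1.4	0.8	3.8	3.9	8.5	58.9	16.9	38.5
REST	median	0.3	1.4	-1.3	2.8	-2.7	0.7	0.9	2.6	82.5	26.3	62.7
REST	iqr	0.9	0.3	0.2	1.8	1.6	1.8	3.0	6.1	110.4	41.3	79.2
TGMHS	median	1.0	1.7	-1.5	4.2	-3.8	9.2	3.9	13.9	127.6	46.5	66.0
TGMHS	iqr	0.9	0.3	0.4	2.2	3.1	8.1	9.7	17.8	75.4	33.6	56.2
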