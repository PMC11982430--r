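feature	label	auc	ci_low	ci_high	threshold	sensitivity	specificity	direction	suspect
ratio_pos_neg	Ratio n +VE peaks >1 g : n -VE peaks <1 g	0.82	0.71	0.93	0.05	1.00	0.87	above	FALSE
mean_pos_g	Mean +VE (g) peak	0.74	0.59	0.88	1.15	0.94	0.90	above	FALSE
mean_neg_g	Mean -VE (g) peak	0.18	0.06	0.33	-1.85	0.81	0.96	below	FALSE
max_pos_g	Max +VE (g) peak	0.74	0.60	0.87	1.65	0.95	0.84	above	FALSE
min_neg_g	Min -VE (g) peak	0.20	0.09	0.40	-6.7	0.83	1.00	below	FALSE
pct_pos_gt2	% peaks >+2 g	0.84	0.72	0.95	-1.00	1.00	1.00	above	TRUE
pct_neg_lt2	% peaks <-2 g	0.79	0.66	0.92	-1.00	1.00	1.00	above	TRUE
pct_abs_gt2	% peaks <-2 g and >+2 g	0.84	0.72	0.96	0.15	0.94	0.82	above	FALSE
total_per_min	Peaks >1 g or <1 g per min	0.60	0.36	0.73	41.70	0.88	0.83	above	FALSE
pos_per_min	+VE peaks >1 g per min	0.78	0.65	0.90	5.10	1.00	0.82	above	FALSE
neg_per_min	-VE peaks <1 g per min	0.46	0.28	0.64	15.50	0.88	0.83	above	FALSE
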