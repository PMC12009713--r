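set_id	category	n_detected	median_rank	ks_statistic	p_value	fdr	detected_members	tie_flag
butyrate_producers	custom	7	-1.6	1	5.77860989760304e-06	2.31144395904122e-05	853,301301,166486,39491,649756,33043,831	FALSE
proteobacteria_bloom	custom	5	0.6	0.842105263157895	0.00263504611330698	0.00527009222661396	562,573,1351,1304,29466	FALSE
acetate_producers	custom	5	0.1	0.526315789473684	0.171372106154714	0.182055930339683	216816,1680,40520,28117,33038	FALSE
propionate_producers	custom	6	0.25	0.5	0.182055930339683	0.182055930339683	165179,817,820,239935,218538,29466	FALSE
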