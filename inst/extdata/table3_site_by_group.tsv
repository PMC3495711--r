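site	key	numerator	denominator
2	TRANSITION	32	139
2	AC_GT	37	138
2	AT_TA	38	143
2	CG_GC	58	134
3	TRANSITION	42	137
3	AC_GT	52	139
3	AT_TA	72	157
3	CG_GC	56	142
4	TRANSITION	37	144
4	AC_GT	42	141
4	AT_TA	38	135
4	CG_GC	41	137
2	ALL	139	554
3	ALL	189	575
4	ALL	162	557
ALL	TRANSITION	111	420
ALL	AC_GT	131	418
ALL	AT_TA	148	435
ALL	CG_GC	155	413
ALL	ALL	490	1686
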