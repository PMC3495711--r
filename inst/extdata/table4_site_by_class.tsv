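site	key	numerator	denominator
2	TC	17	65
2	GA	16	71
2	CA	19	74
2	AA	15	63
2	TG	19	72
2	GG	15	62
2	CC	18	69
2	TT	20	78
3	TC	26	81
3	GA	17	60
3	CA	37	79
3	AA	26	85
3	TG	27	70
3	GG	21	69
3	CC	16	67
3	TT	19	64
4	TC	24	73
4	GA	26	82
4	CA	21	75
4	AA	19	71
4	TG	14	60
4	GG	16	62
4	CC	22	66
4	TT	22	68
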