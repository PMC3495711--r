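snp_type	terminal_class	strength
A/G	TG	Strong
C/T	GT	Strong
G/A	AC	Strong
T/C	CA	Strong
A/C	TC	Weak
G/T	CT	Weak
C/A	AG	Weak
T/G	GA	Weak
A/T	TT	Strong_and_Medium
T/A	AA	Strong_and_Medium
G/C	CC	Strong_and_Medium
C/G	GG	Strong_and_Medium
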