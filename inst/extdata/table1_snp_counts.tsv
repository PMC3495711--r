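snp_type	count	change
A/G	201247	transition
C/T	202316	transition
G/A	202801	transition
T/C	200023	transition
A/C	79813	transversion
G/T	79800	transversion
C/A	80029	transversion
T/G	79782	transversion
A/T	99848	transversion
T/A	99743	transversion
G/C	48372	transversion
C/G	48339	transversion
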