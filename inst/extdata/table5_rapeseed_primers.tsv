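primer_name	snp_type	mismatch_site	mismatch_class	forward	reverse
Br94494	C/G	2	CT	AGTTACATAGGTCCACAATCATAGAATAAACTTTTC	TACCATTCGGAGCCTAAATAGAGGTAAAAGGTG
Br27005	T/A	3	CA	AAGATTGTTTCAAACGCAAAAATATACAACAAAAT	CAACGAATTTCACACTTTAGTAATGCACTGAGATTT
Br31054	T/A	3	CA	CAAGTGAGACTGAATCCACAATAAAGGATGCTACT	TCGGATAAAATCCCCAGCTCTACTATACATTCC
Br43193	T/A	3	CA	CCTTTTATTTGATCACAGGGGTTTGTAGGAACT	TCAGCCAGTAACGTCCCCCACATC
Br51190	T/A	3	CA	AAATAATGGCATGCTCCTCTTTAATCTACCAAACT	TATTCGGTTCCGAAAATAATGCGATGC
Br34590	T/A	3	CA	AAGTGACGGTTCTTTAAGTTATCAGAGTCTCCTAAT	AGATTTGGGATTAAAATCAAGTTGTGGGTTAGTTTT
Br03637	T/A	3	CA	ATTACAGAATGTGTGTGCAAACAGAAATACATTACT	TGTGTCCCCATTTCGTGTAATCATAAAGCTAG
Br39807	T/A	3	CA	CGAGACTCGGGTCGTTGAGTGGAAAT	ATCCTAAAGACTTCTCCCACAAATCCACCAT
Br68275	T/A	3	CA	TGCCGCATGTATGTCGGAGATGATAAT	AACCGAAACCCTAGTAGGCTAGGCGC
Br29253	T/A	3	CA	TGGCGCTAAATCCAAGAAGAAGTCCATT	AATTACCACCTTTCTTACCCTTGTTACTCATGACAG
Br61715	T/A	3	CA	TGAATAGATTCTTCCGCATCACCTTTTAAAGTTAAT	CTTGTTTCAAGAGAAATTGAACAAGCTGCAGT
Br24494	C/G	2	GT	GTCAATAATACTAGCAAACATACAACAGCGAGATTC	TTGCAAATTTTAGTCAAAGTCGGTAGAAAATAGATC
Br06710	T/A	3	CA	TCTTGTCGATGCTGAGCTGGCAAATACT	GGTCAAGCTCACACACACTCCACGTC
Br00855	T/A	3	CA	CACTATGGGCTATGGTGGGTCCTTCAAT	TGATTGGAGTTCTGTGCTCGTAGTTTTGC
Br71197	C/G	2	GT	TATGGCACACAGACAGAGTTCCAGGAAATC	TCTTCCAGTTCGATATCTTGGTCTGTCCC
Br07809	C/G	2	GT	CTCCGCCCACATGTTATAATATGTCAGTATATCTTC	TAGTGAATGGAGAAAGAGAACAAAGCCTACAGTACA
Br02456	T/A	3	CA	GCCTTCAGAAGGTCTGGAAACTGGATT	GTTCGATGGACTTCACTACCTCCCATAGCT
Br77080	T/A	3	CA	CGGATAGTTTCGGGTTCGGTTCGATT	ACCGAACGGGTACCCGAATATATAAAAATATTAATT
Br77646	T/A	3	CA	TCCACCAGAATTGTGTGATGGCACTTACT	GAAAAACGTCAGGTCAATGTATCAACTTCGATAA
Br14184	G/A	3	AC	GATTAACCGATGAAAGTCTCAGTGCCACAG	TCGTCTGTGACTCCCAAACACTTGGATAG
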