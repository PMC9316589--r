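guide_id	gene	spacer	is_nontargeting
g1_1	g1	CGGCTTGTCAACACGCAGGC	FALSE
g1_2	g1	GGACTATAGCCCTGGGAGAC	FALSE
g1_3	g1	ACCTAGGCACAGGCAGTGTA	FALSE
g2_1	g2	GCTTCTCGTTCAGGCACAAA	FALSE
g2_2	g2	GGGACTTAGAGCTTACGGTG	FALSE
g2_3	g2	AACGTATGTTTTATCTGATA	FALSE
g3_1	g3	ATAGTGTCGACAGGTCGTTT	FALSE
g3_2	g3	ATCGTGATGATGGGTTGGAT	FALSE
g3_3	g3	CCCCTCCATTATAACTAGTC	FALSE
NTC_0001	non-targeting	GAGCTATTGATACAGCGCGG	TRUE
NTC_0002	non-targeting	GTACTGCATCTAGCCGGCAA	TRUE
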