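guide_id	gene	zt16_vehicle	zt16_drug	zt28_vehicle	zt28_drug
g1_1	g1	10	40	10	40
g1_2	g1	10	25	10	25
g1_3	g1	10	10	10	10
g2_1	g2	10	60	10	10
g2_2	g2	10	10	10	10
g2_3	g2	10	10	10	10
g3_1	g3	10	4	10	1
g3_2	g3	10	3	10	10
g3_3	g3	10	10	10	10
NTC_0001	non-targeting	10	50	10	50
NTC_0002	non-targeting	10	50	10	50
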