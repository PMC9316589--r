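sample	timepoint	treatment	role
zt16_vehicle	ZT16	vehicle	screen
zt16_drug	ZT16	drug	screen
zt28_vehicle	ZT28	vehicle	screen
zt28_drug	ZT28	drug	screen
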