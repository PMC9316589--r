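pyrimidine_like	pyrimidine_like	g2	g1
unrelated	unrelated	g3
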