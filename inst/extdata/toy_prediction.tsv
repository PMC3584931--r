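target	term	score
A	x01	0.800
A	t01	0.800
A	t02	0.600
A	t03	0.600
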