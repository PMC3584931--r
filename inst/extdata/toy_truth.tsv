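target	term
A	t01
A	t02
A	t03
A	t04
A	t05
A	t06
A	t07
A	t08
A	t09
A	t10
A	t11
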