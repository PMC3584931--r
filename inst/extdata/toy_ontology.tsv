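child_id	parent_id	relation
t01	MFO	is_a
t02	t01	is_a
t07	t01	is_a
x01	t01	is_a
t03	t02	is_a
t05	t02	is_a
t04	t03	is_a
t11	t04	is_a
t06	t05	is_a
t08	t07	part_of
t09	t08	is_a
t10	t09	is_a
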