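orthologue	position	wt_aa	mut_aa
SsIGPS	174	A	W
TmIGPS	131	I	M
TmIGPS	178	I	C
TmIGPS	178	I	W
TtIGPS	78	G	M
TtIGPS	153	L	C
TtIGPS	153	L	Y
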