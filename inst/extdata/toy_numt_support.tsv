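read_id	position	alt
r1	600	T
r2	600	T
r3	700	G
r4	700	G
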