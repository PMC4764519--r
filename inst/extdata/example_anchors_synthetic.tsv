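# SYNTHETIC example anchor table -- plausible ring placements for a
# full-scale (L = 60 nm) pore, NOT the measured anchor coordinates of any
# real NPC model. Columns: nup_name ring_z(nm) ring_radius(nm) copies sequence_id
nup_name	ring_z	ring_radius	copies	sequence_id
Nup159	14.0	34.0	8	Nup159
Nup42	12.0	33.0	8	Nup42
Nsp1	8.0	31.5	16	Nsp1
Nup100	5.0	30.8	8	Nup100
Nup116	5.0	30.8	8	Nup116
Nup49	2.0	30.2	16	Nup49
Nup57	-2.0	30.2	16	Nup57
Nup145	-5.0	30.8	8	Nup145
Nup60	-12.0	33.0	8	Nup60
Nup1	-14.0	34.0	8	Nup1
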