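sample_id	species	replicate	batch
H_1	H	1	b1
H_2	H	2	b1
H_3	H	3	b1
C_1	C	1	b1
C_2	C	2	b1
C_3	C	3	b1
G_1	G	1	b1
G_2	G	2	b1
G_3	G	3	b1
O_1	O	1	b1
O_2	O	2	b1
O_3	O	3	b1
M_1	M	1	b1
M_2	M	2	b1
M_3	M	3	b1
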