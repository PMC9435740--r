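chr1	5	80	MIR	0	+
chr2	5	80	MIR	0	+
chr3	5	80	L1	0	+
chr4	5	80	MIR	0	+
chr5	5	80	MIR	0	+
chr6	5	80	L1	0	+
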