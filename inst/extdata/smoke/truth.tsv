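class	gene_id	transcript_id	feature	species	effect	mechanism
exon_gain	g002	g002.tx	ex|chr2|476|566	H	NA	Alu
gain	g001	g001.tg	jx|chr1|+|699|944	H	NA	canonicity
diu	g003	g003.t2	NA	H	0.4	none
deu	g004	g004.t1	g004:519-678	C	0.4	none
novel_gene	g005	NA	NA	NA	NA	none
nnc	g006	g006.tn	jx|chr6|+|685|977	NA	NA	none
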