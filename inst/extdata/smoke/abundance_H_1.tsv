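target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	110	41909.9097902087
g001.t2	864	864	45	19049.9589955494
g001.t3	777	777	21	9885.38412742023
g001.tg	924	924	44	17417.1053673594
g002.t1	948	948	128	49385.2101555508
g002.t2	762	762	67	32159.9307767385
g002.t3	768	768	28	13334.9712968846
g003.t1	729	729	67	33615.730112311
g003.t2	579	579	238	150346.619388709
g003.t3	612	612	12	7171.74926891271
g004.t1	978	978	240	89756.8620158401
g004.t2	819	819	123	54930.8707739798
g004.t3	822	822	29	12903.9138305619
g005.t1	762	762	206	98879.7871643005
g005.t2	651	651	157	88209.2110540462
g005.t3	606	606	62	37420.9095516535
g006.t1	846	846	219	94682.3493906455
g006.t2	693	693	126	66501.6750390088
g006.t3	699	699	54	28256.0765187205
g006.tn	738	738	56	27754.0866016459
g002.tx	1038	1038	75	26427.6887799529
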