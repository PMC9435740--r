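target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	191	72302.6564561828
g001.t2	864	864	66	27760.1822344856
g001.t3	777	777	27	12628.008485747
g001.tg	924	924	0	0
g002.t1	948	948	155	59417.651272892
g002.t2	762	762	96	45783.4358398387
g002.t3	768	768	39	18454.2120536069
g003.t1	729	729	90	44864.9409850272
g003.t2	579	579	62	38913.9436315728
g003.t3	612	612	58	34440.4399914473
g004.t1	978	978	166	61682.4127284944
g004.t2	819	819	72	31947.7821519754
g004.t3	822	822	51	22547.0889548841
g005.t1	762	762	394	187902.851259338
g005.t2	651	651	136	75918.9231783501
g005.t3	606	606	104	62366.7100425526
g006.t1	846	846	241	103523.464889919
g006.t2	693	693	86	45098.0056135208
g006.t3	699	699	64	33273.2266189386
g006.tn	738	738	43	21174.0636112262
g002.tx	1038	1038	0	0
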