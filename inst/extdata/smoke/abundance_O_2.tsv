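target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	217	76478.8965866568
g001.t2	864	864	72	28194.9849167398
g001.t3	777	777	24	10450.6507799499
g001.tg	924	924	0	0
g002.t1	948	948	192	68524.5203039753
g002.t2	762	762	95	42181.4734974848
g002.t3	768	768	61	26873.3449987677
g003.t1	729	729	177	82148.3511154396
g003.t2	579	579	83	48501.2175769825
g003.t3	612	612	45	24877.9278677116
g004.t1	978	978	166	57427.8220390039
g004.t2	819	819	126	52052.2798462889
g004.t3	822	822	40	16464.2247688992
g005.t1	762	762	366	162509.676842941
g005.t2	651	651	191	99267.1358358951
g005.t3	606	606	47	26240.8770512232
g006.t1	846	846	213	85184.8480463204
g006.t2	693	693	85	41499.1119986647
g006.t3	699	699	45	21781.5334120737
g006.tn	738	738	64	29341.1225149813
g002.tx	1038	1038	0	0
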