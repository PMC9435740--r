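target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	135	50867.9181459911
g001.t2	864	864	94	39354.6033392853
g001.t3	777	777	29	13500.7659200571
g001.tg	924	924	60	23488.7933718862
g002.t1	948	948	164	62577.3170253543
g002.t2	762	762	57	27058.3501598973
g002.t3	768	768	33	15542.9749890528
g003.t1	729	729	70	34733.7712687152
g003.t2	579	579	167	104332.433149943
g003.t3	612	612	25	14776.4468107454
g004.t1	978	978	216	79890.7180697775
g004.t2	819	819	81	35775.2391356421
g004.t3	822	822	46	20242.6535579613
g005.t1	762	762	315	149532.987725748
g005.t2	651	651	107	59454.4296746454
g005.t3	606	606	79	47155.8845152422
g006.t1	846	846	247	105610.723673736
g006.t2	693	693	92	48021.5331158563
g006.t3	699	699	37	19147.2309918466
g006.tn	738	738	65	31859.460928534
g002.tx	1038	1038	49	17075.7644300822
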