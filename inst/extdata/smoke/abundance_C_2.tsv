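target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	198	73897.1292015347
g001.t2	864	864	105	43542.0794958538
g001.t3	777	777	21	9683.4894940586
g001.tg	924	924	0	0
g002.t1	948	948	160	60470.7360810411
g002.t2	762	762	71	33383.8935707244
g002.t3	768	768	38	17727.8466518833
g003.t1	729	729	203	99770.4932645736
g003.t2	579	579	47	29083.9174959722
g003.t3	612	612	42	24588.468421188
g004.t1	978	978	370	135549.050279818
g004.t2	819	819	7	3062.3000964117
g004.t3	822	822	5	2179.3741562054
g005.t1	762	762	205	96390.1152394154
g005.t2	651	651	150	82555.0947650157
g005.t3	606	606	86	50846.309521608
g006.t1	846	846	288	121970.761286866
g006.t2	693	693	158	81687.84932506
g006.t3	699	699	40	20502.9534352028
g006.tn	738	738	27	13108.1382175671
g002.tx	1038	1038	0	0
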