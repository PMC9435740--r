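target_id	length	eff_length	est_counts	tpm
g001.t1	960	960	213	73717.7304888922
g001.t2	864	864	100	38454.7368225833
g001.t3	777	777	56	23945.8685511438
g001.tg	924	924	0	0
g002.t1	948	948	197	69043.2895052559
g002.t2	762	762	88	38369.9547256517
g002.t3	768	768	45	19467.7105164328
g003.t1	729	729	174	79302.2128252385
g003.t2	579	579	97	55661.7371956315
g003.t3	612	612	50	27144.5201100588
g004.t1	978	978	118	40087.293747812
g004.t2	819	819	74	30020.0494931464
g004.t3	822	822	26	10509.0901214418
g005.t1	762	762	241	105081.353282751
g005.t2	651	651	209	106666.705936633
g005.t3	606	606	89	48795.6343681414
g006.t1	846	846	283	111142.371276164
g006.t2	693	693	137	65682.6881416384
g006.t3	699	699	61	28994.54148065
g006.tn	738	738	62	27912.5114107337
g002.tx	1038	1038	0	0
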