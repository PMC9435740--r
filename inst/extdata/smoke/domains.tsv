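transcript_id	domains
g001.t1	D1+D2+D3+D4+D5
g001.t2	D1+D2+D3+D4+D5
g001.t3	D1+D2+D3+D4+D5
g001.tg	D1+D2+D3+D4+D5
g002.t1	D1+D2+D3+D4+D5
g002.t2	D1+D2+D3+D4+D5
g002.t3	D1+D2+D3+D4+D5
g003.t1	D1+D2+D3+D4
g003.t2	D1+D3+D4
g003.t3	D1+D2+D3+D4
g004.t1	D1+D2+D3+D4+D5
g004.t2	D1+D2+D3+D4+D5
g004.t3	D1+D2+D3+D4+D5
g005.t1	D1+D2+D3+D4
g005.t2	D1+D2+D3+D4
g005.t3	D1+D2+D3+D4
g006.t1	D1+D2+D3+D4
g006.t2	D1+D2+D3+D4
g006.t3	D1+D2+D3+D4
g006.tn	D1+D2+D3+D4
g002.tx	D1+D2+D3+D4+D5
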