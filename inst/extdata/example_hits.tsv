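n1	Hcf	97.8	45	1	0	2	136	10	54	3.1e-21	98.2
n1	CG5254	31.0	42	29	0	5	130	3	44	0.0021	22.1
n2	arg	99.0	60	0	0	1	180	1	60	8.4e-35	131.0
n3	AMPKalpha	95.5	44	2	0	4	135	12	55	6.7e-19	91.7
n3	svr	33.3	30	20	0	10	99	40	69	0.15	17.9
n4	Asterix	98.1	52	1	0	3	158	5	56	1.2e-27	112.4
n5	Tango5	28.6	35	25	0	1	105	11	45	1.3	14.6
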