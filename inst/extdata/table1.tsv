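species	total	total_new	pip	pip_new	tip	tip_new	nip	nip_new	sip	sip_new	xip	xip_new
Rice	41	3	13	0	11	0	13	1	2	0	2	2
Arabidopsis	41	3	14	1	12	1	11	1	4	0	0	0
Pepper	73	10	19	2	31	3	16	3	5	2	2	0
Potato	56	9	19	3	11	0	13	1	3	0	10	5
Tomato	48	4	15	2	11	0	12	0	3	0	7	2
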