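interval	background	PD	NPD	T	cM_printed	se_printed
1b	ColCol	3976	3	742	8.05	0.29
1c	ColCol	3022	11	1695	18.62	0.04
2a	ColCol	6787	2	430	3.06	0.15
2b	ColCol	6582	2	635	4.48	0.18
3b	ColCol	4363	22	2557	19.37	0.35
3c	ColCol	6185	5	736	5.53	0.21
5c	ColCol	5356	1	666	5.58	0.21
5d	ColCol	5358	1	664	5.56	0.21
1b	ColLer	4395	2	652	6.58	0.25
1c	ColLer	3156	18	1891	19.73	0.04
2a	ColLer	5920	0	283	2.28	0.13
2b	ColLer	5796	0	407	3.28	0.16
3b	ColLer	2758	2	1056	13.99	0.38
3c	ColLer	3576	2	238	3.28	0.22
5c	ColLer	5458	0	676	5.51	0.20
5d	ColLer	5540	2	594	4.94	0.20
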