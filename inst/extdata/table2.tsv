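strain	construct	rate_e5	sd_e5
Wild Type	5ORID-DR	210	30
Wild Type	0ORID-DR	3	2
Wild Type	5ORID	9	3
Wild Type	DL-6ORID	240	40
sml1D	5ORID-DR	160	50
sml1D	0ORID-DR	18	3
sml1D	5ORID	6	2
sml1D	DL-6ORID	130	30
rad9 (ofm14)	5ORID-DR	1500	100
rad9 (ofm14)	0ORID-DR	19	4
rad9 (ofm14)	5ORID	39	11
rad9 (ofm14)	DL-6ORID	ND	ND
rad9D	5ORID-DR	2100	400
rad9D	0ORID-DR	32	6
rad9D	5ORID	30	8
rad9D	DL-6ORID	9600	1000
rad17D	5ORID-DR	1100	100
rad17D	0ORID-DR	12	3
rad17D	5ORID	ND	ND
rad17D	DL-6ORID	ND	ND
rad24D	5ORID-DR	980	180
rad24D	0ORID-DR	12	3
rad24D	5ORID	24	5
rad24D	DL-6ORID	1500	300
mec1D sml1D	5ORID-DR	1400	200
mec1D sml1D	0ORID-DR	33	7
mec1D sml1D	5ORID	260	40
mec1D sml1D	DL-6ORID	610	100
mrc1D	5ORID-DR	1200	200
mrc1D	0ORID-DR	150	20
mrc1D	5ORID	530	100
mrc1D	DL-6ORID	460	100
chk1D	5ORID-DR	410	50
chk1D	0ORID-DR	9	2
chk1D	5ORID	N.D.	N.D.
chk1D	DL-6ORID	1100	200
rad53D sml1D	5ORID-DR	490	90
rad53D sml1D	0ORID-DR	67	11
rad53D sml1D	5ORID	N.D.	N.D.
rad53D sml1D	DL-6ORID	1200	200
rad53D chk1D sml1D	5ORID-DR	880	140
rad53D chk1D sml1D	0ORID-DR	39	7
rad53D chk1D sml1D	5ORID	N.D.	N.D.
rad53D chk1D sml1D	DL-6ORID	9000	1000
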