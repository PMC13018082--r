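##CanRisk 2.0
##FamID	Name	Target	IndivID	FathID	MothID	Sex	MZtwin	Dead	Age	Yob	BC1	BC2	OC	PAN	BRCA1	BRCA2	PALB2
FAM1	gf	0	gf	0	0	M	0	1	80	0	0	0	0	0	0:0	0:0	0:0
FAM1	gm	0	gm	0	0	F	0	1	78	0	55	0	0	0	0:0	0:0	0:0
FAM1	f	0	f	0	0	M	0	0	65	0	0	0	0	0	0:0	0:0	0:0
FAM1	m	0	m	gf	gm	F	0	0	62	0	45	0	0	0	S:P	0:0	0:0
FAM1	a1	0	a1	gf	gm	F	0	0	60	0	50	0	0	0	S:P	0:0	0:0
FAM1	a2	0	a2	gf	gm	F	0	0	75	0	0	0	0	0	S:N	0:0	0:0
FAM1	q	0	q	gf	gm	F	0	0	81	0	0	0	0	0	0:0	0:0	0:0
FAM1	p	1	p	f	m	F	0	0	45	0	40	0	0	0	S:P	0:0	0:0
FAM1	s	0	s	f	m	F	0	0	50	0	0	0	0	0	S:N	0:0	0:0
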