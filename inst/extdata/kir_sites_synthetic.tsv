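gene	allele	position	base
KIR2DL1	KIR2DL1*00101	85	A
KIR2DL1	KIR2DL1*00101	310	C
KIR2DL1	KIR2DL1*00101	515	C
KIR2DL1	KIR2DL1*00101	700	G
KIR2DL1	KIR2DL1*00101	910	T
KIR2DL1	KIR2DL1*00201	85	G
KIR2DL1	KIR2DL1*00201	310	C
KIR2DL1	KIR2DL1*00201	515	C
KIR2DL1	KIR2DL1*00201	700	G
KIR2DL1	KIR2DL1*00201	910	T
KIR2DL1	KIR2DL1*00302	85	A
KIR2DL1	KIR2DL1*00302	310	T
KIR2DL1	KIR2DL1*00302	515	C
KIR2DL1	KIR2DL1*00302	700	G
KIR2DL1	KIR2DL1*00302	910	T
KIR2DL1	KIR2DL1*00401	85	G
KIR2DL1	KIR2DL1*00401	310	C
KIR2DL1	KIR2DL1*00401	515	C
KIR2DL1	KIR2DL1*00401	700	A
KIR2DL1	KIR2DL1*00401	910	T
KIR3DL1S1	KIR3DL1*00101	88	G
KIR3DL1S1	KIR3DL1*00101	374	C
KIR3DL1S1	KIR3DL1*00101	800	G
KIR3DL1S1	KIR3DL1*00101	1009	C
KIR3DL1S1	KIR3DL1*00101	1229	G
KIR3DL1S1	KIR3DL1*00401	88	T
KIR3DL1S1	KIR3DL1*00401	374	C
KIR3DL1S1	KIR3DL1*00401	800	G
KIR3DL1S1	KIR3DL1*00401	1009	C
KIR3DL1S1	KIR3DL1*00401	1229	G
KIR3DL1S1	KIR3DL1*00501	88	G
KIR3DL1S1	KIR3DL1*00501	374	A
KIR3DL1S1	KIR3DL1*00501	800	G
KIR3DL1S1	KIR3DL1*00501	1009	C
KIR3DL1S1	KIR3DL1*00501	1229	G
KIR3DL1S1	KIR3DL1*00701	88	G
KIR3DL1S1	KIR3DL1*00701	374	C
KIR3DL1S1	KIR3DL1*00701	800	C
KIR3DL1S1	KIR3DL1*00701	1009	C
KIR3DL1S1	KIR3DL1*00701	1229	G
KIR3DL1S1	KIR3DL1*008	88	G
KIR3DL1S1	KIR3DL1*008	374	C
KIR3DL1S1	KIR3DL1*008	800	G
KIR3DL1S1	KIR3DL1*008	1009	T
KIR3DL1S1	KIR3DL1*008	1229	G
KIR3DL1S1	KIR3DS1*01301	88	T
KIR3DL1S1	KIR3DS1*01301	374	A
KIR3DL1S1	KIR3DS1*01301	800	C
KIR3DL1S1	KIR3DS1*01301	1009	T
KIR3DL1S1	KIR3DS1*01301	1229	A
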