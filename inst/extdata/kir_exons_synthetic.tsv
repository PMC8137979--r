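gene	exon	start	end	signal_peptide_length
KIR2DL1	1	1	63	21
KIR2DL1	2	64	180	21
KIR2DL1	3	181	360	21
KIR2DL1	4	361	420	21
KIR2DL1	5	421	570	21
KIR2DL1	6	571	720	21
KIR2DL1	7	721	870	21
KIR2DL1	8	871	930	21
KIR2DL1	9	931	1053	21
KIR3DL1S1	1	1	54	18
KIR3DL1S1	2	55	84	18
KIR3DL1S1	3	85	192	18
KIR3DL1S1	4	193	618	18
KIR3DL1S1	5	619	903	18
KIR3DL1S1	6	904	960	18
KIR3DL1S1	7	961	1050	18
KIR3DL1S1	8	1051	1140	18
KIR3DL1S1	9	1141	1290	18
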