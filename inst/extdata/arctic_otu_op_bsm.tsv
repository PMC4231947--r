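	GU-GC	GAU-C	AUG-U
HGB_0010	0	2	3
HGB_0011	7	5	0
HGB_0012	25	19	18
HGB_0013	22	41	11
HGB_0014	42	66	9
HGB_0015	18	45	7
HGB_0016	28	54	30
HGB_0017	41	43	16
HGB_0018	24	61	16
HGB_0019	34	49	15
HGB_0023	20	24	11
HGB_0024	51	95	22
HGB_0025	36	58	30
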