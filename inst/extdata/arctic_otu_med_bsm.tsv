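	-	UC-	UU
HGB_0010	0	2	0
HGB_0011	7	4	1
HGB_0012	25	15	2
HGB_0013	22	24	13
HGB_0014	43	30	25
HGB_0015	18	24	18
HGB_0016	28	35	15
HGB_0017	41	29	6
HGB_0018	26	29	21
HGB_0019	35	25	16
HGB_0023	21	10	6
HGB_0024	52	52	24
HGB_0025	37	34	14
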