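Bait	Prey	AvgP	BFDR	SpecSum	FoldChange
BAIT01	TP01_01	1.00	0.00	24	48.2
BAIT01	TP01_02	0.99	0.00	18	36.5
BAIT01	TP01_03	0.97	0.01	15	30.1
BAIT01	TP01_04	0.95	0.02	12	22.4
BAIT01	TP01_05	0.90	0.04	9	18.0
BAIT01	BG0001	0.40	0.35	11	1.1
BAIT01	BG0007	0.10	0.60	6	0.9
BAIT02	TP02_01	1.00	0.00	30	52.7
BAIT02	TP02_02	0.98	0.01	16	28.9
BAIT02	TP02_03	0.92	0.03	10	19.5
BAIT02	TP02_04	0.88	0.05	8	15.2
BAIT02	TP02_05	0.75	0.08	6	10.4
BAIT02	BG0013	0.22	0.49	7	1.3
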