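BAIT01_R1	BAIT01	BG0001	12
BAIT01_R1	BAIT01	BG0002	3
BAIT01_R1	BAIT01	BG0003	3
BAIT01_R1	BAIT01	BG0004	4
BAIT01_R1	BAIT01	BG0006	6
BAIT01_R1	BAIT01	BG0008	2
BAIT01_R1	BAIT01	BG0009	4
BAIT01_R1	BAIT01	BG0010	2
BAIT01_R1	BAIT01	BG0011	6
BAIT01_R1	BAIT01	BG0012	7
BAIT01_R1	BAIT01	BG0013	2
BAIT01_R1	BAIT01	BG0014	4
BAIT01_R1	BAIT01	BG0015	1
BAIT01_R1	BAIT01	BG0016	11
BAIT01_R1	BAIT01	BG0017	1
BAIT01_R1	BAIT01	BG0018	8
BAIT01_R1	BAIT01	BG0019	2
BAIT01_R1	BAIT01	BG0020	1
BAIT01_R1	BAIT01	BG0021	5
BAIT01_R1	BAIT01	BG0023	1
BAIT01_R1	BAIT01	BG0024	5
BAIT01_R1	BAIT01	BG0025	6
BAIT01_R1	BAIT01	BG0026	8
BAIT01_R1	BAIT01	BG0027	4
BAIT01_R1	BAIT01	BG0028	5
BAIT01_R1	BAIT01	BG0031	9
BAIT01_R1	BAIT01	BG0032	3
BAIT01_R1	BAIT01	BG0033	1
BAIT01_R1	BAIT01	BG0034	2
BAIT01_R1	BAIT01	BG0035	4
BAIT01_R1	BAIT01	BG0036	4
BAIT01_R1	BAIT01	BG0037	6
BAIT01_R1	BAIT01	BG0038	3
BAIT01_R1	BAIT01	BG0039	5
BAIT01_R1	BAIT01	TP01_01	15
BAIT01_R1	BAIT01	TP01_02	5
BAIT01_R1	BAIT01	TP01_03	9
BAIT01_R1	BAIT01	TP01_04	19
BAIT01_R1	BAIT01	TP01_05	24
BAIT01_R2	BAIT01	BG0001	11
BAIT01_R2	BAIT01	BG0002	1
BAIT01_R2	BAIT01	BG0004	1
BAIT01_R2	BAIT01	BG0006	7
BAIT01_R2	BAIT01	BG0007	5
BAIT01_R2	BAIT01	BG0008	1
BAIT01_R2	BAIT01	BG0009	3
BAIT01_R2	BAIT01	BG0010	11
BAIT01_R2	BAIT01	BG0011	2
BAIT01_R2	BAIT01	BG0012	2
BAIT01_R2	BAIT01	BG0013	8
BAIT01_R2	BAIT01	BG0015	3
BAIT01_R2	BAIT01	BG0016	1
BAIT01_R2	BAIT01	BG0017	4
BAIT01_R2	BAIT01	BG0018	6
BAIT01_R2	BAIT01	BG0019	13
BAIT01_R2	BAIT01	BG0020	9
BAIT01_R2	BAIT01	BG0021	10
BAIT01_R2	BAIT01	BG0022	2
BAIT01_R2	BAIT01	BG0024	10
BAIT01_R2	BAIT01	BG0025	10
BAIT01_R2	BAIT01	BG0026	10
BAIT01_R2	BAIT01	BG0027	5
BAIT01_R2	BAIT01	BG0028	8
BAIT01_R2	BAIT01	BG0030	4
BAIT01_R2	BAIT01	BG0031	1
BAIT01_R2	BAIT01	BG0032	4
BAIT01_R2	BAIT01	BG0033	12
BAIT01_R2	BAIT01	BG0034	1
BAIT01_R2	BAIT01	BG0035	6
BAIT01_R2	BAIT01	BG0036	4
BAIT01_R2	BAIT01	BG0037	1
BAIT01_R2	BAIT01	BG0038	7
BAIT01_R2	BAIT01	BG0040	6
BAIT01_R2	BAIT01	TP01_01	27
BAIT01_R2	BAIT01	TP01_02	3
BAIT01_R2	BAIT01	TP01_03	9
BAIT01_R2	BAIT01	TP01_04	8
BAIT01_R2	BAIT01	TP01_05	20
BAIT02_R1	BAIT02	BG0001	2
BAIT02_R1	BAIT02	BG0002	3
BAIT02_R1	BAIT02	BG0003	12
BAIT02_R1	BAIT02	BG0004	3
BAIT02_R1	BAIT02	BG0005	3
BAIT02_R1	BAIT02	BG0006	4
BAIT02_R1	BAIT02	BG0007	3
BAIT02_R1	BAIT02	BG0008	4
BAIT02_R1	BAIT02	BG0009	4
BAIT02_R1	BAIT02	BG0010	8
BAIT02_R1	BAIT02	BG0011	11
BAIT02_R1	BAIT02	BG0012	11
BAIT02_R1	BAIT02	BG0014	12
BAIT02_R1	BAIT02	BG0015	5
BAIT02_R1	BAIT02	BG0016	3
BAIT02_R1	BAIT02	BG0018	2
BAIT02_R1	BAIT02	BG0019	3
BAIT02_R1	BAIT02	BG0020	6
BAIT02_R1	BAIT02	BG0021	1
BAIT02_R1	BAIT02	BG0022	7
BAIT02_R1	BAIT02	BG0023	10
BAIT02_R1	BAIT02	BG0024	2
BAIT02_R1	BAIT02	BG0025	20
BAIT02_R1	BAIT02	BG0026	11
BAIT02_R1	BAIT02	BG0027	5
BAIT02_R1	BAIT02	BG0028	13
BAIT02_R1	BAIT02	BG0029	7
BAIT02_R1	BAIT02	BG0030	7
BAIT02_R1	BAIT02	BG0031	2
BAIT02_R1	BAIT02	BG0032	2
BAIT02_R1	BAIT02	BG0033	3
BAIT02_R1	BAIT02	BG0034	4
BAIT02_R1	BAIT02	BG0035	8
BAIT02_R1	BAIT02	BG0036	7
BAIT02_R1	BAIT02	BG0037	4
BAIT02_R1	BAIT02	BG0038	2
BAIT02_R1	BAIT02	BG0039	2
BAIT02_R1	BAIT02	BG0040	1
BAIT02_R1	BAIT02	TP02_01	32
BAIT02_R1	BAIT02	TP02_02	11
BAIT02_R1	BAIT02	TP02_03	7
BAIT02_R1	BAIT02	TP02_05	9
BAIT02_R2	BAIT02	BG0001	2
BAIT02_R2	BAIT02	BG0002	5
BAIT02_R2	BAIT02	BG0003	4
BAIT02_R2	BAIT02	BG0004	4
BAIT02_R2	BAIT02	BG0005	1
BAIT02_R2	BAIT02	BG0006	12
BAIT02_R2	BAIT02	BG0007	3
BAIT02_R2	BAIT02	BG0008	2
BAIT02_R2	BAIT02	BG0009	9
BAIT02_R2	BAIT02	BG0010	6
BAIT02_R2	BAIT02	BG0012	2
BAIT02_R2	BAIT02	BG0013	2
BAIT02_R2	BAIT02	BG0014	13
BAIT02_R2	BAIT02	BG0015	1
BAIT02_R2	BAIT02	BG0016	6
BAIT02_R2	BAIT02	BG0018	10
BAIT02_R2	BAIT02	BG0019	11
BAIT02_R2	BAIT02	BG0020	5
BAIT02_R2	BAIT02	BG0021	4
BAIT02_R2	BAIT02	BG0022	4
BAIT02_R2	BAIT02	BG0023	10
BAIT02_R2	BAIT02	BG0024	6
BAIT02_R2	BAIT02	BG0025	1
BAIT02_R2	BAIT02	BG0026	4
BAIT02_R2	BAIT02	BG0027	2
BAIT02_R2	BAIT02	BG0028	7
BAIT02_R2	BAIT02	BG0029	7
BAIT02_R2	BAIT02	BG0030	8
BAIT02_R2	BAIT02	BG0031	10
BAIT02_R2	BAIT02	BG0032	4
BAIT02_R2	BAIT02	BG0033	6
BAIT02_R2	BAIT02	BG0034	1
BAIT02_R2	BAIT02	BG0036	19
BAIT02_R2	BAIT02	BG0037	2
BAIT02_R2	BAIT02	BG0038	8
BAIT02_R2	BAIT02	BG0039	2
BAIT02_R2	BAIT02	TP02_01	16
BAIT02_R2	BAIT02	TP02_02	3
BAIT02_R2	BAIT02	TP02_03	62
BAIT02_R2	BAIT02	TP02_04	10
BAIT02_R2	BAIT02	TP02_05	3
CTRL01	CTRL01	BG0001	11
CTRL01	CTRL01	BG0002	11
CTRL01	CTRL01	BG0003	13
CTRL01	CTRL01	BG0004	3
CTRL01	CTRL01	BG0005	7
CTRL01	CTRL01	BG0006	4
CTRL01	CTRL01	BG0007	4
CTRL01	CTRL01	BG0008	5
CTRL01	CTRL01	BG0009	6
CTRL01	CTRL01	BG0010	1
CTRL01	CTRL01	BG0011	1
CTRL01	CTRL01	BG0012	3
CTRL01	CTRL01	BG0013	8
CTRL01	CTRL01	BG0014	3
CTRL01	CTRL01	BG0015	2
CTRL01	CTRL01	BG0016	1
CTRL01	CTRL01	BG0017	3
CTRL01	CTRL01	BG0018	3
CTRL01	CTRL01	BG0019	15
CTRL01	CTRL01	BG0020	10
CTRL01	CTRL01	BG0021	5
CTRL01	CTRL01	BG0022	6
CTRL01	CTRL01	BG0023	3
CTRL01	CTRL01	BG0024	4
CTRL01	CTRL01	BG0025	12
CTRL01	CTRL01	BG0026	3
CTRL01	CTRL01	BG0027	1
CTRL01	CTRL01	BG0028	4
CTRL01	CTRL01	BG0029	7
CTRL01	CTRL01	BG0030	5
CTRL01	CTRL01	BG0031	14
CTRL01	CTRL01	BG0032	1
CTRL01	CTRL01	BG0033	7
CTRL01	CTRL01	BG0034	2
CTRL01	CTRL01	BG0035	2
CTRL01	CTRL01	BG0036	3
CTRL01	CTRL01	BG0037	1
CTRL01	CTRL01	BG0038	2
CTRL01	CTRL01	BG0039	4
CTRL01	CTRL01	BG0040	4
CTRL02	CTRL02	BG0001	4
CTRL02	CTRL02	BG0002	7
CTRL02	CTRL02	BG0003	2
CTRL02	CTRL02	BG0004	2
CTRL02	CTRL02	BG0005	2
CTRL02	CTRL02	BG0006	4
CTRL02	CTRL02	BG0007	2
CTRL02	CTRL02	BG0008	2
CTRL02	CTRL02	BG0009	11
CTRL02	CTRL02	BG0010	7
CTRL02	CTRL02	BG0011	2
CTRL02	CTRL02	BG0012	2
CTRL02	CTRL02	BG0013	1
CTRL02	CTRL02	BG0014	5
CTRL02	CTRL02	BG0015	3
CTRL02	CTRL02	BG0016	2
CTRL02	CTRL02	BG0017	13
CTRL02	CTRL02	BG0018	20
CTRL02	CTRL02	BG0019	4
CTRL02	CTRL02	BG0020	5
CTRL02	CTRL02	BG0021	4
CTRL02	CTRL02	BG0022	6
CTRL02	CTRL02	BG0024	2
CTRL02	CTRL02	BG0025	11
CTRL02	CTRL02	BG0026	11
CTRL02	CTRL02	BG0027	4
CTRL02	CTRL02	BG0028	7
CTRL02	CTRL02	BG0029	5
CTRL02	CTRL02	BG0030	4
CTRL02	CTRL02	BG0031	4
CTRL02	CTRL02	BG0032	7
CTRL02	CTRL02	BG0033	3
CTRL02	CTRL02	BG0034	19
CTRL02	CTRL02	BG0035	13
CTRL02	CTRL02	BG0036	6
CTRL02	CTRL02	BG0037	9
CTRL02	CTRL02	BG0038	10
CTRL02	CTRL02	BG0039	18
CTRL02	CTRL02	BG0040	11
CTRL03	CTRL03	BG0001	5
CTRL03	CTRL03	BG0002	4
CTRL03	CTRL03	BG0003	3
CTRL03	CTRL03	BG0004	4
CTRL03	CTRL03	BG0005	1
CTRL03	CTRL03	BG0006	5
CTRL03	CTRL03	BG0007	9
CTRL03	CTRL03	BG0008	5
CTRL03	CTRL03	BG0009	3
CTRL03	CTRL03	BG0010	4
CTRL03	CTRL03	BG0011	6
CTRL03	CTRL03	BG0012	13
CTRL03	CTRL03	BG0013	8
CTRL03	CTRL03	BG0014	5
CTRL03	CTRL03	BG0015	7
CTRL03	CTRL03	BG0016	5
CTRL03	CTRL03	BG0017	3
CTRL03	CTRL03	BG0018	5
CTRL03	CTRL03	BG0019	5
CTRL03	CTRL03	BG0020	3
CTRL03	CTRL03	BG0021	5
CTRL03	CTRL03	BG0022	6
CTRL03	CTRL03	BG0023	4
CTRL03	CTRL03	BG0024	3
CTRL03	CTRL03	BG0025	9
CTRL03	CTRL03	BG0026	9
CTRL03	CTRL03	BG0027	10
CTRL03	CTRL03	BG0028	8
CTRL03	CTRL03	BG0029	3
CTRL03	CTRL03	BG0030	5
CTRL03	CTRL03	BG0031	2
CTRL03	CTRL03	BG0032	6
CTRL03	CTRL03	BG0033	4
CTRL03	CTRL03	BG0034	4
CTRL03	CTRL03	BG0035	3
CTRL03	CTRL03	BG0036	3
CTRL03	CTRL03	BG0037	7
CTRL03	CTRL03	BG0038	6
CTRL03	CTRL03	BG0039	7
CTRL03	CTRL03	BG0040	1
CTRL04	CTRL04	BG0001	17
CTRL04	CTRL04	BG0002	1
CTRL04	CTRL04	BG0003	4
CTRL04	CTRL04	BG0004	2
CTRL04	CTRL04	BG0005	10
CTRL04	CTRL04	BG0006	4
CTRL04	CTRL04	BG0007	2
CTRL04	CTRL04	BG0008	5
CTRL04	CTRL04	BG0009	12
CTRL04	CTRL04	BG0010	6
CTRL04	CTRL04	BG0012	8
CTRL04	CTRL04	BG0013	7
CTRL04	CTRL04	BG0014	8
CTRL04	CTRL04	BG0015	4
CTRL04	CTRL04	BG0017	2
CTRL04	CTRL04	BG0018	4
CTRL04	CTRL04	BG0019	1
CTRL04	CTRL04	BG0020	6
CTRL04	CTRL04	BG0021	7
CTRL04	CTRL04	BG0022	7
CTRL04	CTRL04	BG0023	13
CTRL04	CTRL04	BG0024	16
CTRL04	CTRL04	BG0025	1
CTRL04	CTRL04	BG0026	6
CTRL04	CTRL04	BG0027	5
CTRL04	CTRL04	BG0028	12
CTRL04	CTRL04	BG0029	5
CTRL04	CTRL04	BG0030	9
CTRL04	CTRL04	BG0031	4
CTRL04	CTRL04	BG0032	6
CTRL04	CTRL04	BG0033	10
CTRL04	CTRL04	BG0034	6
CTRL04	CTRL04	BG0035	2
CTRL04	CTRL04	BG0036	7
CTRL04	CTRL04	BG0037	1
CTRL04	CTRL04	BG0038	6
CTRL04	CTRL04	BG0039	3
CTRL04	CTRL04	BG0040	3
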