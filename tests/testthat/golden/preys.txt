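BG0001	100	BG0001
BG0002	100	BG0002
BG0003	100	BG0003
BG0004	100	BG0004
BG0005	100	BG0005
BG0006	100	BG0006
BG0007	100	BG0007
BG0008	100	BG0008
BG0009	100	BG0009
BG0010	100	BG0010
BG0011	100	BG0011
BG0012	100	BG0012
BG0013	100	BG0013
BG0014	100	BG0014
BG0015	100	BG0015
BG0016	100	BG0016
BG0017	100	BG0017
BG0018	100	BG0018
BG0019	100	BG0019
BG0020	100	BG0020
BG0021	100	BG0021
BG0022	100	BG0022
BG0023	100	BG0023
BG0024	100	BG0024
BG0025	100	BG0025
BG0026	100	BG0026
BG0027	100	BG0027
BG0028	100	BG0028
BG0029	100	BG0029
BG0030	100	BG0030
BG0031	100	BG0031
BG0032	100	BG0032
BG0033	100	BG0033
BG0034	100	BG0034
BG0035	100	BG0035
BG0036	100	BG0036
BG0037	100	BG0037
BG0038	100	BG0038
BG0039	100	BG0039
BG0040	100	BG0040
TP01_01	100	TP01_01
TP01_02	100	TP01_02
TP01_03	100	TP01_03
TP01_04	100	TP01_04
TP01_05	100	TP01_05
TP02_01	100	TP02_01
TP02_02	100	TP02_02
TP02_03	100	TP02_03
TP02_04	100	TP02_04
TP02_05	100	TP02_05
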