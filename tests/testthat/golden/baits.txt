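BAIT01_R1	BAIT01	T
BAIT01_R2	BAIT01	T
BAIT02_R1	BAIT02	T
BAIT02_R2	BAIT02	T
CTRL01	CTRL01	C
CTRL02	CTRL02	C
CTRL03	CTRL03	C
CTRL04	CTRL04	C
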