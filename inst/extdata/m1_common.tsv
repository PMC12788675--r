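# Published multi-code intercomparison values (per-code results with
# one-s.d. uncertainties, N = 100000 histories each, plus the published
# MV/SD/RSD summary cells). Used as desk-scale inputs and reference
# outputs for the statistics and variability layers.
energy_eV	code	value	u
20	G4DNA-2	0.5975	0.0016
20	G4DNA-4	0.6123	0.0015
20	G4DNA-6	0.6088	0.0015
20	PARTRAC	0.6208	0.0015
20	MCwater	0.6035	0.0015
20	PTra	0.6085	0.0015
20	PHITS	0.6223	0.0015
50	G4DNA-2	1.824	0.002
50	G4DNA-4	1.836	0.002
50	G4DNA-6	1.936	0.002
50	PARTRAC	1.857	0.002
50	MCwater	1.696	0.003
50	PTra	1.760	0.002
50	PHITS	1.973	0.002
100	G4DNA-2	3.751	0.003
100	G4DNA-4	3.701	0.004
100	G4DNA-6	3.882	0.004
100	PARTRAC	3.826	0.003
100	MCwater	3.376	0.004
100	PTra	3.473	0.004
100	PHITS	4.002	0.004
300	G4DNA-2	5.710	0.012
300	G4DNA-4	5.258	0.012
300	G4DNA-6	5.235	0.013
300	PARTRAC	5.257	0.012
300	MCwater	5.465	0.012
300	PTra	4.577	0.011
300	PHITS	5.150	0.012
600	G4DNA-2	3.374	0.010
600	G4DNA-4	3.234	0.009
600	G4DNA-6	2.841	0.008
600	PARTRAC	2.856	0.010
600	MCwater	3.376	0.011
600	PTra	2.503	0.009
600	PHITS	3.641	0.012
1000	G4DNA-2	2.308	0.008
1000	G4DNA-4	2.290	0.007
1000	G4DNA-6	2.040	0.007
1000	PARTRAC	1.793	0.007
1000	MCwater	2.288	0.008
1000	PTra	1.575	0.006
1000	PHITS	2.111	0.008
5000	G4DNA-2	7.208	0.016
5000	G4DNA-4	7.285	0.016
5000	G4DNA-6	6.364	0.014
5000	PARTRAC	7.103	0.017
5000	MCwater	7.614	0.017
5000	PTra	6.073	0.015
5000	PHITS	7.316	0.015
10000	G4DNA-2	4.344	0.013
10000	G4DNA-4	4.352	0.013
10000	G4DNA-6	3.908	0.012
10000	PARTRAC	4.045	0.014
10000	MCwater	4.587	0.014
10000	PTra	3.402	0.012
10000	PHITS	4.143	0.013
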