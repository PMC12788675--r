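# Published multi-code intercomparison values (per-code results with
# one-s.d. uncertainties, N = 100000 histories each, plus the published
# MV/SD/RSD summary cells). Used as desk-scale inputs and reference
# outputs for the statistics and variability layers.
energy_eV	code	value	u
20	G4DNA-2	0.7680	0.0013
20	G4DNA-4	0.4370	0.0016
20	G4DNA-6	0.8330	0.0012
20	PARTRAC	0.2080	0.0013
20	MCwater	0.2970	0.0014
20	PTra	0.6220	0.0015
20	PHITS	0.4550	0.0016
50	G4DNA-2	2.206	0.002
50	G4DNA-4	1.771	0.002
50	G4DNA-6	2.429	0.002
50	PARTRAC	1.212	0.002
50	MCwater	1.419	0.002
50	PTra	1.8426	0.0020
50	PHITS	1.9027	0.0016
100	G4DNA-2	4.303	0.004
100	G4DNA-4	3.648	0.004
100	G4DNA-6	4.829	0.003
100	PARTRAC	2.808	0.003
100	MCwater	3.167	0.003
100	PTra	3.723	0.003
100	PHITS	4.093	0.002
300	G4DNA-2	5.344	0.013
300	G4DNA-4	4.545	0.011
300	G4DNA-6	6.655	0.015
300	PARTRAC	4.437	0.010
300	MCwater	5.215	0.012
300	PTra	5.015	0.012
300	PHITS	6.040	0.012
600	G4DNA-2	2.905	0.010
600	G4DNA-4	2.541	0.009
600	G4DNA-6	3.587	0.011
600	PARTRAC	2.498	0.008
600	MCwater	2.989	0.010
600	PTra	2.768	0.009
600	PHITS	3.759	0.011
1000	G4DNA-2	1.826	0.007
1000	G4DNA-4	1.668	0.007
1000	G4DNA-6	2.261	0.008
1000	PARTRAC	1.572	0.006
1000	MCwater	1.873	0.007
1000	PTra	1.761	0.007
1000	PHITS	2.198	0.007
5000	G4DNA-2	7.119	0.017
5000	G4DNA-4	6.575	0.016
5000	G4DNA-6	8.112	0.017
5000	PARTRAC	6.470	0.016
5000	MCwater	6.500	0.016
5000	PTra	6.529	0.016
5000	PHITS	7.304	0.013
10000	G4DNA-2	4.024	0.014
10000	G4DNA-4	3.976	0.013
10000	G4DNA-6	4.532	0.014
10000	PARTRAC	3.606	0.013
10000	MCwater	3.709	0.013
10000	PTra	3.593	0.012
10000	PHITS	4.063	0.011
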