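# Published multi-code intercomparison values (per-code results with
# one-s.d. uncertainties, N = 100000 histories each, plus the published
# MV/SD/RSD summary cells). Used as desk-scale inputs and reference
# outputs for the statistics and variability layers.
energy_eV	code	value	u
50	G4DNA-2	0.8893	0.0010
50	G4DNA-4	0.6859	0.0015
50	G4DNA-6	0.9332	0.0008
50	PARTRAC	0.3140	0.0015
50	MCwater	0.4401	0.0016
50	PTra	0.7408	0.0014
50	PHITS	0.8202	0.0012
100	G4DNA-2	0.9621	0.0006
100	G4DNA-4	0.9506	0.0007
100	G4DNA-6	0.9886	0.0003
100	PARTRAC	0.9151	0.0009
100	MCwater	0.9549	0.0007
100	PTra	0.9633	0.0006
100	PHITS	0.9961	0.0002
300	G4DNA-2	0.8140	0.0012
300	G4DNA-4	0.7807	0.0013
300	G4DNA-6	0.8861	0.0010
300	PARTRAC	0.8124	0.0012
300	MCwater	0.8184	0.0012
300	PTra	0.8154	0.0012
300	PHITS	0.9245	0.0008
600	G4DNA-2	0.5900	0.0016
600	G4DNA-4	0.5550	0.0016
600	G4DNA-6	0.6840	0.0015
600	PARTRAC	0.5650	0.0016
600	MCwater	0.5920	0.0016
600	PTra	0.5830	0.0016
600	PHITS	0.7494	0.0014
1000	G4DNA-2	0.4170	0.0016
1000	G4DNA-4	0.3930	0.0015
1000	G4DNA-6	0.5020	0.0016
1000	PARTRAC	0.3810	0.0015
1000	MCwater	0.4280	0.0016
1000	PTra	0.4090	0.0016
1000	PHITS	0.5380	0.0016
5000	G4DNA-2	0.9033	0.0009
5000	G4DNA-4	0.9016	0.0009
5000	G4DNA-6	0.9541	0.0007
5000	PARTRAC	0.9018	0.0009
5000	MCwater	0.8906	0.0010
5000	PTra	0.9082	0.0009
5000	PHITS	0.9768	0.0005
10000	G4DNA-2	0.6880	0.0015
10000	G4DNA-4	0.7100	0.0014
10000	G4DNA-6	0.7745	0.0013
10000	PARTRAC	0.6660	0.0015
10000	MCwater	0.6720	0.0015
10000	PTra	0.6750	0.0015
10000	PHITS	0.8246	0.0012
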