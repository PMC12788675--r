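# Published multi-code intercomparison values (per-code results with
# one-s.d. uncertainties, N = 100000 histories each, plus the published
# MV/SD/RSD summary cells). Used as desk-scale inputs and reference
# outputs for the statistics and variability layers.
energy_eV	code	value	u
50	G4DNA-2	0.7021	0.0014
50	G4DNA-4	0.6982	0.0015
50	G4DNA-6	0.7398	0.0014
50	PARTRAC	0.7186	0.0014
50	MCwater	0.6152	0.0015
50	PTra	0.6809	0.0015
50	PHITS	0.7657	0.0013
100	G4DNA-2	0.9703	0.0005
100	G4DNA-4	0.9614	0.0006
100	G4DNA-6	0.9630	0.0006
100	PARTRAC	0.9760	0.0005
100	MCwater	0.8985	0.0010
100	PTra	0.9449	0.0007
100	PHITS	0.9729	0.0005
300	G4DNA-2	0.8688	0.0011
300	G4DNA-4	0.8528	0.0011
300	G4DNA-6	0.8138	0.0012
300	PARTRAC	0.8151	0.0012
300	MCwater	0.8350	0.0012
300	PTra	0.7911	0.0013
300	PHITS	0.8410	0.0012
600	G4DNA-2	0.6780	0.0015
600	G4DNA-4	0.6779	0.0015
600	G4DNA-6	0.6447	0.0015
600	PARTRAC	0.5846	0.0016
600	MCwater	0.6454	0.0015
600	PTra	0.5486	0.0016
600	PHITS	0.6621	0.0015
1000	G4DNA-2	0.5238	0.0016
1000	G4DNA-4	0.5262	0.0016
1000	G4DNA-6	0.4966	0.0016
1000	PARTRAC	0.4155	0.0016
1000	MCwater	0.5058	0.0016
1000	PTra	0.3735	0.0015
1000	PHITS	0.4654	0.0016
5000	G4DNA-2	0.9329	0.0008
5000	G4DNA-4	0.9345	0.0008
5000	G4DNA-6	0.9278	0.0008
5000	PARTRAC	0.9059	0.0009
5000	MCwater	0.9246	0.0008
5000	PTra	0.8902	0.0010
5000	PHITS	0.9459	0.0007
10000	G4DNA-2	0.7706	0.0013
10000	G4DNA-4	0.7764	0.0013
10000	G4DNA-6	0.7615	0.0013
10000	PARTRAC	0.6934	0.0015
10000	MCwater	0.7568	0.0014
10000	PTra	0.6554	0.0015
10000	PHITS	0.7565	0.0014
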