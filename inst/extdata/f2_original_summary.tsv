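# Published multi-code intercomparison values (per-code results with
# one-s.d. uncertainties, N = 100000 histories each, plus the published
# MV/SD/RSD summary cells). Used as desk-scale inputs and reference
# outputs for the statistics and variability layers.
energy_eV	MV	u_MV	SD	u_SD	RSD	u_RSD
50	0.69	0.09	0.2317	0.0010	0.3363	0.0008
100	0.962	0.011	0.0266	0.0010	0.0277	0.0002
300	0.84	0.02	0.0503	0.0010	0.0602	0.0004
600	0.62	0.03	0.0720	0.0010	0.1167	0.0008
1000	0.44	0.02	0.0588	0.0010	0.1342	0.0013
5000	0.919	0.013	0.0325	0.0010	0.0353	0.0003
10000	0.72	0.02	0.0608	0.0010	0.0849	0.0007
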