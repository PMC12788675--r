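# Published multi-code intercomparison values (per-code results with
# one-s.d. uncertainties, N = 100000 histories each, plus the published
# MV/SD/RSD summary cells). Used as desk-scale inputs and reference
# outputs for the statistics and variability layers.
energy_eV	MV	u_MV	SD	u_SD	RSD	u_RSD
50	0.703	0.020	0.0479	0.0005	0.0681	0.0007
100	0.955	0.011	0.0271	0.0003	0.0283	0.0003
300	0.831	0.011	0.0263	0.0004	0.0317	0.0005
600	0.63	0.02	0.0494	0.0005	0.0778	0.0009
1000	0.47	0.02	0.0582	0.0005	0.1231	0.0012
5000	0.923	0.008	0.0189	0.0003	0.0205	0.0003
10000	0.739	0.019	0.0458	0.0005	0.0620	0.0007
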