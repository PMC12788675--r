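# Published multi-code intercomparison values (per-code results with
# one-s.d. uncertainties, N = 100000 histories each, plus the published
# MV/SD/RSD summary cells). Used as desk-scale inputs and reference
# outputs for the statistics and variability layers.
energy_eV	MV	u_MV	SD	u_SD	RSD	u_RSD
20	0.611	0.004	0.0089	0.0005	0.0145	0.0009
50	1.84	0.04	0.0953	0.0009	0.0518	0.0005
100	3.72	0.09	0.2224	0.0014	0.0599	0.0004
300	5.24	0.14	0.346	0.004	0.0661	0.0008
600	3.12	0.16	0.396	0.004	0.1271	0.0011
1000	2.06	0.12	0.281	0.002	0.1368	0.0012
5000	7.0	0.2	0.559	0.005	0.0800	0.0008
10000	4.11	0.16	0.385	0.004	0.0936	0.0011
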