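# Published multi-code intercomparison values (per-code results with
# one-s.d. uncertainties, N = 100000 histories each, plus the published
# MV/SD/RSD summary cells). Used as desk-scale inputs and reference
# outputs for the statistics and variability layers.
energy_eV	MV	u_MV	SD	u_SD	RSD	u_RSD
20	0.52	0.10	0.2338	0.0010	0.4521	0.0010
50	1.83	0.17	0.4202	0.0010	0.2301	0.0004
100	3.8	0.3	0.6846	0.0012	0.1804	0.0003
300	5.3	0.3	0.794	0.005	0.1493	0.0008
600	3.0	0.2	0.491	0.004	0.1633	0.0012
1000	1.88	0.11	0.259	0.003	0.1380	0.0013
5000	6.9	0.3	0.613	0.006	0.0883	0.0008
10000	3.93	0.14	0.331	0.005	0.0843	0.0012
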