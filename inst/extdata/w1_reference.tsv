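# Published mean Wasserstein-1 distances of each member ICSD to the
# family-mean ICSD, and the same normalized by the family-mean M1.
# phase 'initial' = original datasets, 'final' = common dataset.
energy_eV	phase	mean_w1	u_mean_w1	w1_over_m1	u_w1_over_m1
20	initial	0.19	0.04	0.37	0.10
50	initial	0.35	0.08	0.19	0.05
100	initial	0.56	0.13	0.15	0.04
300	initial	0.66	0.15	0.12	0.03
600	initial	0.39	0.09	0.13	0.03
1000	initial	0.23	0.04	0.12	0.02
5000	initial	0.70	0.12	0.103	0.018
10000	initial	0.40	0.01	0.103	0.004
20	final	0.007	0.003	0.011	0.005
50	final	0.08	0.02	0.045	0.011
100	final	0.18	0.05	0.049	0.012
300	final	0.32	0.08	0.061	0.015
600	final	0.37	0.06	0.12	0.02
1000	final	0.26	0.05	0.13	0.02
5000	final	0.62	0.15	0.09	0.02
10000	final	0.40	0.11	0.10	0.03
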