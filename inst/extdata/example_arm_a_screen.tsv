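outcome	term	beta	se	t	p
hippocampus_volume	income_low	-0.425	0.267	-1.590	0.116
hippocampus_volume	education_low	0.005	0.279	0.019	0.985
hippocampus_volume	ctq	0.030	0.115	0.260	0.796
hippocampus_volume	tei	-0.167	0.101	-1.644	0.104
amygdala_volume	income_low	-0.649	0.283	-2.299	0.024
amygdala_volume	education_low	0.091	0.294	0.310	0.757
amygdala_volume	ctq	0.145	0.118	1.228	0.223
amygdala_volume	tei	-0.146	0.106	-1.380	0.171
frontal_pole_sa	income_low	0.556	0.285	1.950	0.055
frontal_pole_sa	education_low	-0.065	0.294	-0.221	0.826
frontal_pole_sa	ctq	-0.004	0.114	-0.037	0.971
frontal_pole_sa	tei	0.109	0.107	1.017	0.312
medial_ofc_sa	income_low	0.271	0.293	0.926	0.357
medial_ofc_sa	education_low	-0.374	0.302	-1.237	0.220
medial_ofc_sa	ctq	-0.052	0.117	-0.440	0.661
medial_ofc_sa	tei	-0.112	0.110	-1.021	0.310
lateral_ofc_sa	income_low	-0.033	0.298	-0.111	0.912
lateral_ofc_sa	education_low	-0.244	0.307	-0.796	0.428
lateral_ofc_sa	ctq	-0.211	0.119	-1.769	0.081
lateral_ofc_sa	tei	-0.093	0.111	-0.834	0.407
sfg_sa	income_low	0.386	0.289	1.336	0.185
sfg_sa	education_low	-0.435	0.298	-1.460	0.148
sfg_sa	ctq	-0.223	0.116	-1.926	0.058
sfg_sa	tei	0.039	0.108	0.358	0.721
rmfg_sa	income_low	-0.050	0.278	-0.181	0.857
rmfg_sa	education_low	-0.543	0.286	-1.897	0.061
rmfg_sa	ctq	-0.231	0.111	-2.079	0.041
rmfg_sa	tei	0.036	0.104	0.346	0.730
rostral_acc_sa	income_low	-0.176	0.291	-0.602	0.549
rostral_acc_sa	education_low	-0.511	0.301	-1.700	0.093
rostral_acc_sa	ctq	-0.229	0.117	-1.961	0.053
rostral_acc_sa	tei	0.029	0.109	0.268	0.790
caudal_acc_sa	income_low	0.121	0.272	0.443	0.659
caudal_acc_sa	education_low	-0.855	0.280	-3.049	0.003
caudal_acc_sa	ctq	-0.110	0.109	-1.006	0.317
caudal_acc_sa	tei	0.044	0.102	0.436	0.664
frontal_pole_ct	income_low	-0.137	0.293	-0.468	0.641
frontal_pole_ct	education_low	0.684	0.302	2.267	0.026
frontal_pole_ct	ctq	-0.079	0.117	-0.671	0.504
frontal_pole_ct	tei	-0.120	0.110	-1.098	0.275
medial_ofc_ct	income_low	-0.002	0.293	-0.008	0.993
medial_ofc_ct	education_low	0.346	0.315	1.099	0.275
medial_ofc_ct	ctq	0.138	0.118	1.172	0.244
medial_ofc_ct	tei	0.022	0.111	0.202	0.840
lateral_ofc_ct	income_low	-0.023	0.304	-0.074	0.941
lateral_ofc_ct	education_low	0.241	0.314	0.769	0.444
lateral_ofc_ct	ctq	0.055	0.122	0.451	0.653
lateral_ofc_ct	tei	-0.112	0.114	-0.983	0.328
sfg_ct	income_low	-0.088	0.248	-0.356	0.723
sfg_ct	education_low	0.553	0.256	2.162	0.034
sfg_ct	ctq	0.070	0.100	0.699	0.487
sfg_ct	tei	-0.170	0.093	-1.831	0.071
rmfg_ct	income_low	-0.078	0.281	-0.276	0.783
rmfg_ct	education_low	0.443	0.290	1.530	0.130
rmfg_ct	ctq	0.072	0.113	0.637	0.526
rmfg_ct	tei	-0.112	0.105	-1.062	0.291
rostral_acc_ct	income_low	-0.063	0.297	-0.211	0.833
rostral_acc_ct	education_low	0.060	0.318	0.188	0.851
rostral_acc_ct	ctq	0.019	0.118	0.163	0.871
rostral_acc_ct	tei	-0.034	0.112	-0.305	0.761
caudal_acc_ct	income_low	-0.124	0.296	-0.419	0.676
caudal_acc_ct	education_low	0.187	0.318	0.589	0.558
caudal_acc_ct	ctq	0.046	0.119	0.388	0.699
caudal_acc_ct	tei	0.004	0.112	0.039	0.969
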