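analysis	endpoint	hr_both	hr_chip_only	hr_mca_only	reri	ap	si
chip_mca	incident_cvd	1.048	1.082	0.995	-0.028	-0.027	0.974
chip_mca	incident_cad	1.069	1.110	1.031	-0.073	-0.068	0.933
chip_mca	cv_death	1.090	1.073	1.148	-0.131	-0.120	0.885
chip_mca	cad_death	1.210	0.798	1.363	0.050	0.041	1.113
chip_mca	any_death	1.406	1.305	1.068	0.032	0.023	1.008
chip_loy	incident_cvd	0.994	1.083	0.993	-0.091	-0.094	0.916
chip_loy	incident_cad	0.918	1.106	1.016	-0.229	-0.258	0.796
chip_loy	cv_death	0.998	1.151	1.046	-0.105	-0.101	0.900
chip_loy	cad_death	0.807	0.902	1.166	-0.230	-0.306	0.775
chip_loy	any_death	1.307	1.342	1.080	-0.111	-0.086	0.907
chip_lox	incident_cvd	1.169	1.090	1.011	0.082	0.069	1.072
chip_lox	incident_cad	1.298	1.209	1.201	-0.029	-0.022	0.963
chip_lox	cv_death	0.000	1.053	1.248	-1.348	NA	NA
chip_lox	cad_death	0.000	1.086	2.111	NA	NA	NA
chip_lox	any_death	1.470	1.310	0.985	0.168	0.115	1.130
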