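phenotype	code	effect	ci_low	ci_high	p	n_cases
Asthma	J45	1.003	1.002	1.004	1.29e-6	28628
Eczema/dermatitis		1.002	1.001	1.003	7.96e-9	11552
Other dermatitis	L30	1.001	1.000	1.001	5.26e-6	1654
Monocyte percentage		1.040	1.032	1.048	1.09e-24	14307
Monocyte count		1.003	1.002	1.003	2.66e-19	14322
Mean corpuscular hemoglobin		1.024	1.018	1.030	2.19e-16	13433
Mean corpuscular volume		1.060	1.045	1.075	1.07e-15	13219
Mean platelet (thrombocyte) volume		0.988	0.985	0.991	9.81e-14	13220
Platelet count		1.761	1.467	2.113	1.21e-9	13258
Red blood cell (erythrocyte) distribution width		0.991	0.988	0.994	1.30e-7	13429
Hemoglobin concentration		1.009	1.005	1.012	4.85e-7	13226
Platelet distribution width		0.996	0.994	0.998	2.10e-6	13220
Lymphocyte count		0.995	0.993	0.997	4.39e-6	14209
Mean sphered cell volume		0.961	0.945	0.978	6.01e-6	20355
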