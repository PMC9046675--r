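phenotype	code	effect	ci_low	ci_high	p	n_cases
Mean platelet (thrombocyte) volume		1.011	1.008	1.015	2.79e-12	13220
Platelet count		0.570	0.475	0.685	1.62e-9	13258
Mean corpuscular hemoglobin		0.986	0.980	0.992	1.63e-6	13433
Monocyte count		0.999	0.998	0.999	6.08e-6	14322
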