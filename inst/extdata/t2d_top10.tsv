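rsid	chrom	position	p_empiric	p_imputed	maf_emp	maf_imp	status
rs2000816	11	84151075	0.2382	1.57e-30	0.50	0.49	Discordant
rs4143896	14	41379353	0.4551	1.06e-19	0.50	0.49	Discordant
rs4982270	14	34950569	0.0853	5.72e-17	0.50	0.49	Discordant
rs10152907	15	52679008	0.3110	2.30e-15	0.50	0.50	Discordant
rs12900200	15	99971327	0.0394	2.80e-15	0.49	0.49	Discordant
rs35143	16	63543734	0.8364	3.62e-15	0.50	0.49	Discordant
rs2572406	8	11129662	0.0291	6.78e-15	0.49	0.48	Discordant
rs2996005	1	217884996	0.0010	5.61e-14	0.48	0.48	Discordant
rs696891	5	60940318	0.4430	9.85e-14	0.50	0.49	Discordant
rs4506565	10	114746031	6.02e-13	1.38e-12	0.35	0.35	Concordant
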