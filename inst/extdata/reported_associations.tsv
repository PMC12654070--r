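metabolite	outcome	or	ci_low	ci_high	p_printed	n_tests
lithocholate sulfate (1)	CLL	2.19	1.45	3.31	2e-4	83
cortisol	AML	2.83	1.01	7.93	NA	83
cholesterol/cortisol ratio	AML	0.35	0.13	0.97	NA	83
thyroxine	AML	0.34	0.12	1.00	NA	83
phosphate/linoleoyl-arachidonoyl-glycerol (18:2/20:4) ratio	CML	6.32	1.80	22.15	NA	83
1,5-anhydroglucitol (1,5-AG)	CML	4.99	1.64	15.14	NA	83
beta-citrylglutamate	CML	0.63	0.46	0.86	NA	83
beta-alanine	CML	0.50	0.26	0.98	NA	83
bilirubin (Z,Z)/etiocholanolone glucuronide ratio	CML	0.67	0.46	0.99	NA	83
choline	ALL	4.14	1.06	16.10	NA	83
beta-hydroxyisovalerate	CLL	2.55	1.42	4.57	NA	83
2'-deoxyuridine	CLL	1.67	1.07	2.59	NA	83
3-methoxytyrosine	CLL	2.24	1.07	4.70	NA	83
pregnenediol sulfate (C21H34O5S)	CLL	2.13	1.05	4.33	NA	83
N-acetylputrescine/(N(1)+N(8))-acetylspermidine ratio	CLL	0.55	0.35	0.87	NA	83
5,6-dihydrothymine	CLL	0.46	0.24	0.88	NA	83
gamma-CEHC	CLL	0.73	0.56	0.96	NA	83
beta-citrylglutamate	CLL	0.83	0.70	0.99	NA	83
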