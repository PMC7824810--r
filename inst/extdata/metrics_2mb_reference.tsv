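# Published per-marker imputation performance summary at the 2-Mb flanking
# window for the 19 ISAG ovine parentage microsatellites in a commercial
# Assaf population: genotype concordance (conc), genotype dosage length r2
# (gd), allelic dosage r2 (ad, with per-marker min/max), and the
# concordance of the naive and random null imputation models.
chrom	pos_bp	id	conc	gd	ad	ad_min	ad_max	naive_conc	random_conc
1	86986507	INRA023	0.98	0.97	0.97	0.93	0.99	0.28	0.13
1	109478015	INRA006	0.93	0.87	0.84	0.60	1.00	0.48	0.11
1	195256010	INRA049	0.97	0.97	0.88	0.32	0.98	0.44	0.16
2	153680836	FCB20	0.96	0.94	0.89	0.52	1.00	0.26	0.10
5	78045895	AE129	0.96	0.96	0.88	0.13	1.00	0.47	0.20
7	23419543	SPS113	0.95	0.93	0.79	0.16	0.94	0.34	0.16
7	92854099	ILSTS005	0.99	0.97	0.97	0.97	0.97	0.41	0.11
9	25256863	ILSTS011	0.98	0.96	0.92	0.83	0.97	0.50	0.18
9	45990219	ILSTS008	0.97	0.86	0.80	0.37	0.97	0.67	0.61
9	51865313	McM042	0.97	0.97	0.93	0.70	0.98	0.48	0.17
14	15564041	CSRD247	0.99	0.97	0.97	0.94	1.00	0.34	0.07
14	39826970	INRA063	0.97	0.95	0.82	0.47	0.98	0.33	0.09
15	23269440	SPS115	0.96	0.95	0.90	0.67	1.00	0.33	0.14
15	30901387	MAF65	0.98	0.97	0.92	0.75	1.00	0.36	0.18
16	33667802	MAF214	0.98	0.98	0.86	0.32	1.00	0.54	0.09
17	14434435	CP49	0.98	0.97	0.92	0.84	0.98	0.39	0.06
20	4668849	INRA132	0.98	0.97	0.95	0.84	0.97	0.29	0.11
20	25764806	HSC	0.98	0.98	0.95	0.77	0.99	0.54	0.09
22	20603037	INRA172	0.96	0.95	0.91	0.72	1.00	0.35	0.12
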