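# Catalogue of the 19 ISAG-recommended ovine parentage microsatellites:
# marker id, chromosome and 1-based position (Oar_v3.1), number of alleles
# and allele length range (bp) observed in a commercial Assaf population.
# The INRA049 position follows the per-marker metric table (195256010); a
# variant transcription (1952560108) exceeds the chromosome length and is
# not used.
id	chrom	pos_bp	n_alleles	range_min_bp	range_max_bp
INRA006	1	109478015	13	104	134
INRA049	1	195256010	9	134	166
INRA023	1	86986507	14	194	220
FCB20	2	153680836	14	87	115
AE129	5	78045895	6	135	161
SPS113	7	23419543	11	126	152
ILSTS005	7	92854099	12	190	214
ILSTS011	9	25256863	8	268	282
ILSTS008	9	45990219	2	168	170
McM042	9	51865313	8	81	107
CSRD247	14	15564041	19	205	257
INRA063	14	39826970	18	167	207
SPS115	15	23269440	12	237	255
MAF65	15	30901387	9	119	137
MAF214	16	33667802	16	183	269
CP49	17	14434435	25	76	136
HSC	20	25764806	17	263	297
INRA132	20	4668849	17	146	180
INRA172	22	20603037	12	126	172
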