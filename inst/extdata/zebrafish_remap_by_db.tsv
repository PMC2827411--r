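# Published remapping summary of the Affymetrix Zebrafish Genome Array
# (249,752 probes, Zv7 genome) across six annotation databases.
# Category counts per database; pct_good_printed is the percentage of good
# probes as printed (three decimals), probe_sets the probe-set count.
db	MULTI_GENOME	NO_GENOME	MULTI_GENE	INTERGENIC	INTRONIC	UNDERPOPULATED_SET	GOOD	probe_sets	pct_good_printed
GenBank	19585	41609	2718	65220	8348	2369	109903	8574	44.005
RefSeq	19585	42398	1674	75916	6912	762	102505	6769	41.043
Ensembl	19585	41972	432	81273	9817	1464	95209	7156	38.121
ZFIN	19585	41613	2228	64394	9049	3884	108999	9195	43.643
Biomart	19585	41488	1592	66806	10068	3126	107087	8732	42.877
UCSC	19585	41077	1487	54532	10911	4378	117782	10251	47.160
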