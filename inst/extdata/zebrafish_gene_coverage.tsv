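# Published gene/transcript coverage of the remapped Affymetrix Zebrafish
# Genome Array probe sets per annotation database, with the printed
# three-decimal summary ratios.
db	transcripts_matched	genes_matched	genes_multi_set	probe_sets	probesets_per_gene_printed	transcripts_per_probeset_printed
GenBank	12803	7069	1296	8574	1.213	1.493
RefSeq	6688	6560	202	6769	1.032	0.988
Ensembl	8076	6347	726	7156	1.127	1.129
ZFIN	25665	7003	1809	9195	1.313	2.791
Biomart	23212	6983	1439	8732	1.250	2.658
UCSC	28356	7725	2069	10251	1.327	2.766
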