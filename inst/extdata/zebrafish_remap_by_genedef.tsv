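# Published remapping summary of the Affymetrix Zebrafish Genome Array
# under four gene-definition (transcript linkage) methods, UCSC transcript
# collection.  GENOME_ISSUES pools the multi-alignment and no-alignment
# probes; NO_GENE pools the intergenic and intronic probes.
method	n_genes_defined	GENOME_ISSUES	MULTI_GENE	NO_GENE	UNDERPOPULATED_SET	GOOD	pct_good_printed
exlink	28110	60662	1487	65443	4378	117782	47.160
exbd	32686	60662	10672	65443	3992	108983	43.636
itbd	29501	60662	4360	65443	4234	115053	46.067
overlap_0	27876	60662	974	65443	4402	118271	47.355
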