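id	species	aliases	sizes_file
hg18	Homo sapiens	ncbi36,grch36	hg18.chrom.sizes
hg19	Homo sapiens	grch37	hg19.chrom.sizes
hg38	Homo sapiens	grch38	hg38.chrom.sizes
mm9	Mus musculus	ncbi37	mm9.chrom.sizes
mm10	Mus musculus	grcm38	mm10.chrom.sizes
dm3	Drosophila melanogaster	bdgp5	dm3.chrom.sizes
dm6	Drosophila melanogaster	bdgp6	dm6.chrom.sizes
toyA	Synthetica exemplaris	toy-a	toyA.chrom.sizes
toyB	Synthetica exemplaris	toy-b	toyB.chrom.sizes
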