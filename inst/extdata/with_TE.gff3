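##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-20
locus	rtracklayer	gene	1001	1610	.	+	.	ID=CG11699;Parent=;genotype=with_TE
locus	rtracklayer	mRNA	1001	1610	.	+	.	ID=CG11699-short;Parent=CG11699;stop_codon_last_base=1500;cleavage_site=1610;
locus	rtracklayer	gene	1583	2789	.	-	.	ID=Kmn1;Parent=;genotype=with_TE
locus	rtracklayer	mRNA	1583	2789	.	-	.	ID=Kmn1-main;Parent=Kmn1;stop_codon_last_base=1978;cleavage_site=1583;
locus	rtracklayer	mRNA	1905	2789	.	-	.	ID=Kmn1-shortUTR;Parent=Kmn1;stop_codon_last_base=1978;cleavage_site=1905;
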