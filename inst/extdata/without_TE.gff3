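##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-20
locus	rtracklayer	gene	1001	1721	.	+	.	ID=CG11699;Parent=;genotype=without_TE
locus	rtracklayer	mRNA	1001	1610	.	+	.	ID=CG11699-short;Parent=CG11699;stop_codon_last_base=1500;cleavage_site=1610;
locus	rtracklayer	mRNA	1001	1721	.	+	.	ID=CG11699-long;Parent=CG11699;stop_codon_last_base=1500;cleavage_site=1721;
locus	rtracklayer	gene	1582	2600	.	-	.	ID=Kmn1;Parent=;genotype=without_TE
locus	rtracklayer	mRNA	1582	2600	.	-	.	ID=Kmn1-main;Parent=Kmn1;stop_codon_last_base=1790;cleavage_site=1582;
locus	rtracklayer	mRNA	1717	2600	.	-	.	ID=Kmn1-shortUTR;Parent=Kmn1;stop_codon_last_base=1790;cleavage_site=1717;
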