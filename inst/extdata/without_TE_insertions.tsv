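# after_base is 1-based: element inserted between after_base and after_base+1
chrom	after_base	length	tsd_length	te_id
locus	1709	186	2	FBti0019627
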