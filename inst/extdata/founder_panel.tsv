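gene	cdna	protein	rsid	chrom	pos	ref	alt
SLC22A12	c.774G>A	p.Trp258*	rs121907892	11	64361219	G	A
SLC22A12	c.269G>A	p.Arg90His	rs121907896	11	64359052	G	A
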