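protein_change	chrom	pos	cdna_change	human_residue	rhesus_macaque	mus_musculus	canis_lupus_familiaris	loxodonta_africana	af_dbsnp	af_gnomad	mutation_taster	pp2_humvar	sift	condel
p.Glu429Lys	11	64367362	c.1285G>A	Glu	Glu	Gly	Glu	Glu	0.00005	0.000044	DC	Bn(0.37)	Tol(0.05)	Neu(0.463)
p.Thr225Lys	11	64361119	c.674C>A	Thr	Thr	Thr	Thr	Thr	NA	NA	DC	Dam(0.998)	Del(0)	Del(0.919)
p.Arg284Gln	11	64366008	c.851G>A	Arg	Arg	Arg	Arg	Arg	NA	0.000019	DC	Dam(0.527)	Del(0.03)	Del(0.542)
p.Asn136Lys	11	64360256	c.408C>A	Asn	Asn	Asp	Asp	Asp	NA	0.000004	PM	Bn(0.345)	Del(0)	Del(0.553)
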