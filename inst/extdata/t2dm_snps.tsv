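rsid	chrom	pos	allele_freq_note
rs864745	chr7	28180556	T=0.65,C=0.35
rs849134	chr7	28196222	A=0.65,G=0.35
rs1531343	chr12	66174894	G=0.81,C=0.19
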