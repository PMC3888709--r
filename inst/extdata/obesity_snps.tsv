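rsid	chrom	pos	allele_freq_note
rs7132908	chr12	50263148	G=0.73,A=0.27
rs1443512	chr12	54342684	A=0.31,C=0.69
rs16933812	chr9	36969205	G=0.40,T=0.60
rs6905288	chr6	43758873	G=0.38,A=0.62
rs6784615	chr3	52506426	C=0.04,T=0.96
rs10195252	chr2	165513091	T=0.60,C=0.40
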