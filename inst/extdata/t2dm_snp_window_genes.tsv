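gene_id	chrom	start	end	percentage
HIBADH	chr7	27565059	27702620	42.9
TMBIM4	chr12	66530717	66563807	42.9
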