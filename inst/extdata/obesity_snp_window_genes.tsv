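gene_id	chrom	start	end	percentage
NCKAP5L	chr12	50184929	50222208	63.6
SP1	chr12	53773979	53810230	63.6
ITGA5	chr12	54789045	54813050	58.3
TOMM5	chr9	37588410	37592636	57.1
HSP90AB1	chr6	44214849	44221614	55.6
BAP1	chr3	52435024	52444009	50.0
GRB14	chr2	165349323	165478360	50.0
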