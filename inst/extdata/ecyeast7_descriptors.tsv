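category	class	count
reactions	enzyme_matched	3239
reactions	not_matched	330
reactions	transport	1674
reactions	exchange	330
reactions	arm	404
reactions	usage	764
metabolites	original	2220
metabolites	enzymes	764
metabolites	pseudo	404
relationships	complexes	226
relationships	isozyme_reactions	373
relationships	promiscuous_enzymes	315
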