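gene_low_in_cancer	gene_high_in_cancer
LOC100130691	LOC441204
ZNF232-AS1	TOB1-AS1
ZNF232-AS1	COPB2-DT
ZNF232-AS1	LINC01547
ZNF232-AS1	ZNF22-AS1
POLR2J4	ZNF503-AS2
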