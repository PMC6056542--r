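# SYNTHETIC curated promoter collection, P. cellulosolvens sigma-I11 style.
# Constructed stand-ins realizing the described architecture: CCC triad
# immediately upstream of the A-tract and the conserved CGCAT pentad in the
# -10 element. Gene labels follow the described sigma-I11 regulon members.
sigma_label	gene_label	specificity_seq	atract_seq	spacer_seq	minus10_seq	utr5
sigI11	Bccel_5622	TACCCC	AAAA	GGCTGTTGCGGT	CGCATTGATG	66
sigI11	Bccel_3806	GTCCCC	AAA	TGGTGGCTGTGGT	CGCATAAATC	139
sigI11	Bccel_5179	ATACCC	AAAA	GGTCGGTGTCGG	CGCATCTATG	94
sigI11	Bccel_5541	TGTCCC	AAA	GTGGCGTTGGTCG	CGCATTCATA	171
sigI11	Bccel_5619	CATCCC	AAAA	TGCGGTGGTTGG	CGCATGTAAG	58
sigI11	Bccel_5627	TTCCCC	AAAAA	GGCTGGTGTCGGTG	CGCATATAAC	203
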