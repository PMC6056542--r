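# SYNTHETIC curated promoter collection, C. thermocellum style.
# These sequences are constructed stand-ins, NOT transcriptions of published
# figure alignments: they realize the promoter architecture described in the
# running text (sigI1: CTC triad immediately upstream of the A-tract, CGAA
# tetrad, AT dyad 3 nt downstream; sigI3: CCC triad up to two nt upstream,
# rgl11A with the CCCCT context, cipA/cel48S with the universal CCCCTCAAA
# nonad, the sigI3 promoter with the CGTA tetrad and GT dyad; sigI2/4/6
# triads are synthetic placeholders). minus10_seq = -10 core tetrad plus
# 6 nt downstream context; the conserved dyad position is context nt 4-5.
sigma_label	gene_label	specificity_seq	atract_seq	spacer_seq	minus10_seq	utr5
sigI1	sigI1	TAGCTC	AAAA	GCTGGTCGTGGC	CGAAGCAATC	52
sigI1	cipA	CCCCTC	AAA	GTATGCTGGTGTT	CGAATGTATG	97
sigI1	man5A	GTACTC	AAAA	TGGCGTTGTCGGTG	CGAACTTATA	133
sigI1	cbm3A	TTCCTC	AAA	GGTTGCGGACGT	CGAAGATATT	64
sigI3	rgl11A	ACCCCT	AAA	GTTGTCGGTTGTG	CGAATACATG	44
sigI3	rga12A	TCCCGT	AAAA	GGTCGTGTTGGC	CGAACATATC	58
sigI3	sigI3	CCCCTC	AAAA	TGTGGTTGCGGTGG	CGTAGCAGTT	39
sigI3	pl11A	ACCCAT	AAAA	GCGGTGGTTGTCG	CGAATTAATA	71
sigI3	cel48S	CCCCTC	AAA	GGTGTTGGCGTC	CGAAATAATG	87
sigI2	sigI2	CATTGT	AAAA	GGCTGTTGGCGG	CGAAGGTATC	48
sigI2	xyn10D	GCTTGT	AAA	TGGCGGTTGTGGT	CGAATCAATG	112
sigI2	ce3B	ACTTGT	AAAA	GTGGCTGGTCGT	CGAACGTATG	76
sigI2	cel9K	TCATGT	AAAAA	GGTGTCGGCTGGTG	CGAAGTAATC	91
sigI4	sigI4	TTGGAG	AAAA	GGCGTTGTCGGT	CGAATGAATC	55
sigI4	cel5E	CAGGAG	AAA	TGTCGTGGCTGGT	CGAAGTCATG	102
sigI4	chi18A	GTCGAG	AAAA	GGTTGGCTGTGG	CGAACGAATT	69
sigI6	sigI6	GTGTAC	AAAA	TGGCGGCTGTCG	CGAAGCTATG	41
sigI6	xyn11B	CTTTAC	AAA	GGTGCTGGTCGGT	CGAATGTATC	123
sigI6	xyn10Z	AGTTAC	AAAA	GTCGGTGGCTGG	CGAACTAATG	85
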