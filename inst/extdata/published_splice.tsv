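# Published splice-site score pairs (consensus-value scale of the original
# tool) with the ref>alt 9-mer/14-mer sequence changes. wt/mut scores are
# inputs to the percent-variation arithmetic; printed_variation is the
# printed result. Scores from other matrices are matrix-relative and are not
# expected to reproduce these absolute values.
gene	variant	strand	matrix	site_position	ref_kmer	alt_kmer	wt_score	mut_score	printed_variation
TLR9	chr3:52223761C>A	-	donor	chr3:52223765	GCAGGCAGG	GCAGTCAGG	46.68	73.82	58.14
TNFRSF1B	chr1:12167150C>T	+	donor	chr1:12167146	GCGGCGCAC	GCGGTGCAC	42.51	69.65	63.84
TNFRSF1B	chr1:12202100G>A	+	acceptor	chr1:12202090	GCGCCCACTCGGAA	GCGCCCACTCAGAA	47.83	75.7	58.27
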