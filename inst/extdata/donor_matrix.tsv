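# Donor (5') splice-site weight matrix, 9-mer: exon positions -3..-1 then
# intron +1..+6 (GT dinucleotide at positions 4-5). Per-position base
# frequencies (%) in the Shapiro-Senapathy consensus-value style; scores are
# min-max normalised to 0-100, so absolute values are matrix-relative.
position	A	C	G	T
1	34	37	19	10
2	60	13	12	15
3	9	3	80	8
4	0	0	100	0
5	0	0	0	100
6	53	3	42	2
7	71	8	12	9
8	7	6	81	6
9	16	17	22	45
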