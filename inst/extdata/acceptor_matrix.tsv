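# Acceptor (3') splice-site weight matrix, 14-mer: polypyrimidine tract
# (positions 1-10), the AG dinucleotide (positions 11-12) and the first two
# exonic bases (13-14). Per-position base frequencies (%) in the
# Shapiro-Senapathy consensus-value style; min-max normalised to 0-100.
position	A	C	G	T
1	10	31	15	44
2	9	31	12	48
3	7	33	10	50
4	7	32	10	51
5	8	33	10	49
6	9	37	8	46
7	6	38	7	49
8	6	41	6	47
9	23	30	10	37
10	2	26	1	71
11	100	0	0	0
12	0	0	100	0
13	28	14	48	10
14	20	17	23	40
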