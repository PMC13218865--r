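# Published gene-burden summary statistics (case cohort N = 371, A = 742
# alleles) used as reconstruction inputs: aggregate case alt-allele counts
# and the reference-panel MAFs as printed, with the printed odds ratios for
# comparison. control odds are reconstructed as maf/(1-maf).
gene	class	case_ac	case_an	population	control_maf	printed_or
FAS	functional	7	742	NFE	3.68e-4	25.917
IKBKE	functional	6	742	NFE	2.57e-5	315.957
LTBR	functional	6	742	NFE	1.69e-4	48.232
TLR1	functional	6	742	NFE	2.18e-4	37.458
TLR2	functional	6	742	NFE	3.75e-4	21.738
TLR4	functional	9	742	NFE	1.23e-4	99.166
TLR5	functional	5	742	NFE	0	Inf
TLR9	functional	8	742	NFE	7.84e-5	139.046
TNFAIP3	functional	7	742	NFE	2.09e-4	45.434
TNFRSF1B	functional	8	742	NFE	3.92e-5	278.400
TNFSF12	functional	5	742	NFE	2.21e-4	30.695
TRAF2	functional	9	742	NFE	1.88e-4	65.240
FAS	synonymous	2	742	NFE	2.65e-4	10.209
FAS	synonymous	2	742	Global	0.02	0.132
FAS	synonymous	2	742	CSVS	4.91e-4	5.500
FAS	missense	2	742	NFE	1.62e-4	16.709
FAS	missense	2	742	CSVS	4.91e-4	5.500
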