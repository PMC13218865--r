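# Curated NF-kB pathway gene set (63 symbols): canonical and non-canonical
# core components, upstream receptors and key regulators. User-replaceable:
# supply any one-symbol-per-line file to analyse a different gene family.
NFKB1
NFKB2
RELA
RELB
REL
NFKBIA
NFKBIB
NFKBIE
CHUK
IKBKB
IKBKG
IKBKE
TBK1
TLR1
TLR2
TLR3
TLR4
TLR5
TLR6
TLR7
TLR8
TLR9
TLR10
MYD88
IRAK1
IRAK2
IRAK4
TRAF1
TRAF2
TRAF3
TRAF5
TRAF6
TNFRSF1A
TNFRSF1B
TNFRSF11A
TNFRSF12A
TNFSF12
LTBR
LTA
LTB
CD40
CD40LG
TNFAIP3
CYLD
FAS
FASLG
FADD
TRADD
RIPK1
MAP3K7
MAP3K14
TAB1
TAB2
TAB3
BCL3
BCL10
MALT1
CARD11
UBE2N
NOD1
NOD2
TNF
IL1B
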