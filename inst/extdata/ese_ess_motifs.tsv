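# Exemplar splicing-regulatory motif sets (pluggable; replace with any
# motif/class table). ESE: SR-protein-style purine-rich exonic enhancers.
# ESS: hnRNP-style exonic silencers. ISE/ISS: intronic counterparts.
motif	class
GAAGAA	ESE
GAGGAA	ESE
AAGAAG	ESE
GAAGGA	ESE
TGGAAG	ESE
CAGAAG	ESE
GAAGAT	ESE
GGAAGA	ESE
TAGGGT	ESS
TAGGGA	ESS
TTAGTT	ESS
TAGACT	ESS
GGGTGG	ESS
TCCTCC	ESS
GGGGCT	ISE
TTTTGT	ISE
CTCTCT	ISS
TTCTTC	ISS
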