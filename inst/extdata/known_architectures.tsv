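# Local reference catalog of TIR-domain architectures considered already known.
# Signatures are ordered N-terminal to C-terminal, comma-separated canonical labels.
# SYNTHETIC compilation of widely documented bilaterian/cnidarian architectures,
# standing in for a live domain-architecture database query.
signature	provenance
LRR,TIR	vertebrate/invertebrate TLR
LRR,LRR,TIR	vertebrate/invertebrate TLR
DD,TIR	MyD88
Ig,Ig,Ig,TIR	IL-1R family
Ig,Ig,TIR	IL-1R family
TIR	single-TIR adaptors (SARM-like fragments)
SAM,SAM,TIR	SARM1
CARD,NACHT,LRR	NLRC-type NLR
PYD,NACHT,LRR	NLRP-type NLR
NACHT,LRR	canonical NLR
RHD,Ank	Class 1 NF-kB
TIR,NB-ARC,LRR	plant TNL resistance protein
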