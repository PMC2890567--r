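# Small editable vertebrate TF consensus library (IUPAC strings).
AP-2alpha	GCCNNNGGC
SP1	GGGGCGGGG
EGR1	GCGSGGGCG
MZF1	AGTGGGGA
MYB	YAACKG
C-Rel	SGGRNWTTCC
NF-kB	GGGRNNYYCC
CREB	TGACGTCA
MYC	CACGTG
MTF-1	TGCRCNC
RUNX1	TGTGGT
AP-1	TGASTCA
GATA1	WGATAR
ETS1	MGGAW
NRF1	GCGCATGCGC
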