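# Synthetic stand-in TFAP2A count matrix, built by stacking the 53
# published high-score promoter 9-mers in tfap2a_reported_sites.tsv;
# not copied from any database.
>MA0003synth TFAP2A_synthetic
A [ 0 0 0 0 0 4 15 0 0 ]
C [ 1 52 52 37 22 16 4 0 25 ]
G [ 51 0 0 11 20 32 33 52 27 ]
T [ 0 0 0 4 10 0 0 0 0 ]
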