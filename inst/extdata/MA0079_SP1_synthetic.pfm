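# Synthetic stand-in for a GC-box (SP1-class) count matrix; hand-constructed
# around the canonical GGGGCGGGGC element, not copied from any database.
>MA0079synth SP1_synthetic
A [ 10 5 2 5 3 5 3 10 20 10 ]
C [ 5 5 2 3 80 5 4 10 15 45 ]
G [ 70 85 95 90 2 85 90 75 60 15 ]
T [ 15 5 1 2 15 5 3 5 5 30 ]
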