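# Published high-score TFAP2A binding sites in human core promoters
# (gene symbol, ENSEMBL gene, 9-mer site, reported LLR score, TSS-relative
# position). Used as a rank-calibration reference and to build the
# synthetic stand-in TFAP2A matrix.
gene_symbol	gene_id	sequence	score	position
DCBLD2	ENSG00000057019	GCCGCGGGG	12.74	-269
DCBLD2	ENSG00000057019	GCCCGCAGC	11.54	-10
PPARG	ENSG00000132170	GCCTGAGGC	11.48	-851
PPARG	ENSG00000132170	GCCGGGGGC	12.82	-280
PPARG	ENSG00000132170	GCCGCGGGG	12.74	-176
PPARG	ENSG00000132170	GCCCCGCGG	11.77	-175
PPARG	ENSG00000132170	GCCGTGGGC	11.94	-134
PPARG	ENSG00000132170	GCCCGGCGC	11.85	10
PPARG	ENSG00000132170	GCCCGCGGC	12.85	42
EREG	ENSG00000124882	CCCTCGGGC	12.75	-101
CXCL1	ENSG00000163739	GCCCGGGGG	13.46	-64
CXCL1	ENSG00000163739	GCCCCCGGG	12.76	-63
CXCL1	ENSG00000163739	GCCCGGAGC	12.14	-56
CXCL1	ENSG00000163739	GCCGCAGGC	11.91	13
CD59	ENSG00000085063	GCCCTGGGG	12.58	-336
CD59	ENSG00000085063	GCCCCAGGG	12.55	-335
CD59	ENSG00000085063	GCCGGGAGC	11.51	-37
CD59	ENSG00000085063	GCCGGGGGG	12.83	3
ADAMTS1	ENSG00000154734	GCCCGCAGC	11.54	-142
ADAMTS1	ENSG00000154734	GCCGGGGGC	12.82	-107
SLIT2	ENSG00000145147	GCCGGGGGC	12.81	-679
SLIT2	ENSG00000145147	GCCCCGAGG	12.06	-248
CASP9	ENSG00000132906	GCCCTGGGG	12.58	-734
CASP9	ENSG00000132906	GCCCCCAGG	11.45	-463
CASP9	ENSG00000132906	GCCCCCAGG	11.45	-370
CASP9	ENSG00000132906	GCCCGCAGG	11.55	-182
CASP9	ENSG00000132906	GCCCTGGGG	12.58	4
CASP9	ENSG00000132906	GCCCCCAGG	11.45	69
CASP9	ENSG00000132906	GCCCCGCGC	11.75	2
TGFBI	ENSG00000120708	GCCCTGGGG	12.58	-899
TGFBI	ENSG00000120708	GCCCCCAGC	11.44	-414
TGFBI	ENSG00000120708	GCCCTGGGC	12.57	-212
TGFBI	ENSG00000120708	GCCCTGGGC	12.57	43
GLO1	ENSG00000124767	GCCGCGGGC	12.72	-24
FASTK	ENSG00000164896	GCCCGGAGG	12.15	-856
FASTK	ENSG00000164896	GCCCCGAGC	12.04	-500
FASTK	ENSG00000164896	GCCCGGGGC	13.45	-413
FASTK	ENSG00000164896	GCCCCGGGG	13.36	-393
FASTK	ENSG00000164896	GCCCCCGGG	12.76	-391
FASTK	ENSG00000164896	GCCCTCGGC	11.97	-66
FASTK	ENSG00000164896	GCCCGGCGC	11.85	-59
FASTK	ENSG00000164896	GCCCGCGGG	12.86	-42
FASTK	ENSG00000164896	GCCGGGAGC	11.51	-2
KRT16	ENSG00000186832	GCCCTCGGG	11.98	-860
KRT16	ENSG00000186832	GCCCCCGGG	12.76	-650
KRT16	ENSG00000186832	GCCTGAGGC	11.48	-502
KRT16	ENSG00000186832	GCCCCGAGG	12.06	-279
KRT16	ENSG00000186832	GCCCTCGGG	11.98	-277
KRT17	ENSG00000186831	GCCCCGGGG	13.36	-525
KRT17	ENSG00000186831	GCCCCGGGG	13.36	-524
KRT17	ENSG00000186831	GCCCCCAGC	11.44	-203
KRT17	ENSG00000186831	GCCTGGGGG	12.30	56
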