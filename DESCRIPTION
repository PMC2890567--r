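Package: cismap
Title: Promoter Motif Scanning, Binding-Site Enrichment and Over-Represented
    Oligonucleotide Analysis
Version: 0.1.0
Authors@R:
    person("cismap", "developers", email = "cismap@example.org",
           role = c("aut", "cre"))
Description: Tools for locating transcription-factor binding sites in core
    promoter regions and for testing whether a regulated gene set is enriched
    for them. Converts JASPAR-style count matrices to log-likelihood-ratio
    position weight matrices, scans promoters on both strands with a
    maximum-score fraction cutoff and percentile score thresholds, and tests
    enrichment of site-carrying genes with Fisher's exact test. A second
    route discovers candidate cis-elements de novo: 5-9 nt oligonucleotides
    over-represented per promoter under a binomial model, stratified by GC
    class, filtered for cross-species conservation of over-representation
    (Benjamini-Yekutieli FDR over one-to-one orthologs) and annotated against
    IUPAC consensus sequences of known transcription factors. Includes a
    seeded two-species synthetic promoter generator with planted sites for
    benchmarking, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
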