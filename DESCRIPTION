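Package: ceRNAnet
Title: lncRNA Classification, Differential Expression, Target Prediction
    and ceRNA Network Inference for Insect Gut Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a bulk RNA-seq
    lncRNA analysis pipeline for two-group (antibiotic vs. control) insect
    gut studies: consensus coding-potential classification of transcripts
    into mRNA and lncRNA (3-of-4 classifier vote), TPM/FPKM normalization
    with low-expression filtering and fold-change/p-value differential
    expression calls, cis/trans/coexpression lncRNA target prediction
    (genomic windows, nearest-neighbor RNA duplex energies, dual Pearson/
    Spearman thresholds), competing endogenous RNA (lncRNA-miRNA-mRNA)
    triad assembly under sign-consistency rules with Cytoscape export,
    pathway-level differential-expression summaries and hypergeometric
    enrichment, Toll/Imd pathway protein characterization (ORF translation,
    molecular weight, isoelectric point, domain-architecture validation),
    and integration of gene expression with gut microbiota genus
    abundances by correlation. A seeded synthetic-data generator with
    ground-truth labels makes every stage verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
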