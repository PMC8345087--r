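Package: dirseq
Title: Dinucleotide-Barcode Parallel Reporter Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for DiR-seq, a dinucleotide-barcode massively
    parallel reporter assay (MPRA) used to screen risk SNPs for allele-specific
    regulatory activity. Covers allele-library design (55-bp SNP-centered
    oligos, sub-library tags and dinucleotide barcodes), simulation of
    plasmid/cDNA barcode counts and paired-end reads from a declared ground
    truth, paired-read merging, demultiplexing and counting,
    plasmid-normalized reporter activity scaled to a negative control, and
    regulatory-SNP calling by fold change and t-test. Companion allele-level
    quantifications are included: comparative-Ct relative expression,
    FAIRE/ChIP percent-of-input and fold enrichment over IgG, getPCR
    allele-remaining fraction, Welch two-sample eQTL tests, and
    under-peak-area allele ratios from Sanger chromatograms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    yaml,
    pheatmap,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
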