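Package: codonDeopt
Title: Relative Codon Deoptimization Index and Its Expected Value
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the Relative Codon Deoptimization Index (RCDI) of
    coding sequences against a reference codon-usage table, together with an
    expected RCDI (eRCDI) significance threshold derived from random coding
    sequences matched to the queries' G+C content and amino-acid composition.
    The eRCDI is a one-sided normal tolerance limit (user-chosen confidence
    and coverage) on the RCDI distribution of the random set, accompanied by
    a Kolmogorov-Smirnov normality check (Lilliefors corrected) and
    chi-square homogeneity tests of the query set. Companion codon-usage
    indices are included: the Codon Adaptation Index (CAI), Wright's
    Effective Number of Codons (ENC), the expected ENC from third-position
    G+C, and per-gene %G+C / %G+C3. Readers are provided for FASTA coding
    sequences and codon-usage-database style tables, and reports can be
    written as TSV or JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, Genetics, SequenceMatching, StatisticalMethod
RoxygenNote: 7.3.3
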