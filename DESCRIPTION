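Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of insects, with an emphasis
    on ants. Parses annotated circular mitochondrial genomes from GenBank
    flat files, computes nucleotide composition and strand-asymmetry skews
    (AT-skew, GC-skew), codon-usage-bias statistics under an arbitrary
    genetic code (RSCU, effective number of codons, codon bias index,
    codon-position GC content, ENC-plot null curve, neutrality-plot
    regression), pairwise Ka/Ks selection statistics by Nei-Gojobori
    pathway counting with Jukes-Cantor or Kimura two-parameter correction,
    control-region and intergenic-spacer characterization (tandem repeats,
    homopolymer runs, motif counts, IUPAC consensus, hairpins), and
    neighbor-joining phylogenies from Kimura two-parameter distances with
    bootstrap supports. A synthetic annotated-mitogenome generator and a
    codon-level sequence evolution simulator make every stage testable
    without downloading data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
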