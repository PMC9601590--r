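Package: mitochar
Title: Characterization of Annotated Animal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytics for circular, annotated mitochondrial genomes of the
    vertebrate type (37 genes plus a control region): resolution of
    IUPAC-ambiguous sites in a primary assembly by flank-anchored voting
    against alternate assemblies; gene organization tables with signed
    intergenic/overlap accounting on the circle; base composition with
    AT- and GC-skew by region and protein-coding codon position; relative
    synonymous codon usage (RSCU); pairwise Ka/Ks by the Nei-Gojobori
    counting method with Jukes-Cantor correction; concatenated
    protein-coding supermatrices with gene-by-codon-position partitions and
    neighbor-joining verification trees. Includes a seeded simulator that
    generates annotated mitogenomes and diverged taxon sets with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
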