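Package: spinsex
Title: Sex-Chromosomal SNP Segregation, Exact Sex-Association Tests and
    X-Y Divergence Dating from Cross RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers sex-chromosomal genes from RNA-seq variant data of a
    dioecious cross and dates X-Y divergence. Calls per-sample genotypes
    from allele read depths with a depth-fraction rule, classifies SNPs into
    the three sex-chromosomal segregation patterns of an XY cross, tests
    genotype-by-sex association with exact log-space Fisher (2x2 and 2x3
    Freeman-Halton) tests, phases X- and Y-linked alleles into coding
    sequences, estimates synonymous and non-synonymous substitution rates by
    the Nei-Gojobori (1986) pathway-counting method with the Jukes-Cantor
    correction, converts synonymous divergence into time via a molecular
    clock, and quantifies allele-specific Y/X expression from pooled male
    read depths. A seeded forward simulator of an XY cross (male-specific Y
    region, pseudoautosomal and autosomal compartments) generates complete
    synthetic datasets with truth tables for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
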